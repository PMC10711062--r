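variable,F1,F2,F3
x1,0.52,0.25,-0.11
x2,0.52,-0.11,0.25
x3,0.52,0.25,-0.11
x4,0.52,-0.11,0.25
x5,0.52,0.25,-0.11
x6,0.52,-0.11,0.25
x7,0.25,0.52,-0.11
x8,-0.11,0.52,0.25
x9,0.25,0.52,-0.11
x10,-0.11,0.52,0.25
x11,0.25,0.52,-0.11
x12,-0.11,0.52,0.25
x13,0.25,-0.11,0.52
x14,-0.11,0.25,0.52
x15,0.25,-0.11,0.52
x16,-0.11,0.25,0.52
x17,0.25,-0.11,0.52
x18,-0.11,0.25,0.52
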