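variable,F1,F2,F3
x1,0.5,0.2,-0.2
x2,0.5,-0.2,0.2
x3,0.5,0.2,-0.2
x4,0.5,-0.2,0.2
x5,0.5,0.2,-0.2
x6,0.5,-0.2,0.2
x7,0.2,0.5,-0.2
x8,-0.2,0.5,0.2
x9,0.2,0.5,-0.2
x10,-0.2,0.5,0.2
x11,0.2,0.5,-0.2
x12,-0.2,0.5,0.2
x13,0.2,-0.2,0.5
x14,-0.2,0.2,0.5
x15,0.2,-0.2,0.5
x16,-0.2,0.2,0.5
x17,0.2,-0.2,0.5
x18,-0.2,0.2,0.5
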