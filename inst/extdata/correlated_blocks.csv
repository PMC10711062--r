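variable,F1,F2,F3
x1,0.48,0.13,0
x2,0.48,0.13,0
x3,0.48,0.13,0
x4,0.13,0.48,0
x5,0.13,0.48,0
x6,0.13,0.48,0
x7,0,0,0.5
x8,0,0,0.5
x9,0,0,0.5
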