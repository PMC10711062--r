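kind,p_per_q,level,position,value
salient,5,0.5,1,0.4
salient,5,0.5,2,0.45
salient,5,0.5,3,0.5
salient,5,0.5,4,0.55
salient,5,0.5,5,0.6
salient,5,0.7,1,0.6
salient,5,0.7,2,0.65
salient,5,0.7,3,0.7
salient,5,0.7,4,0.75
salient,5,0.7,5,0.8
salient,8,0.5,1,0.38
salient,8,0.5,2,0.42
salient,8,0.5,3,0.45
salient,8,0.5,4,0.48
salient,8,0.5,5,0.52
salient,8,0.5,6,0.55
salient,8,0.5,7,0.58
salient,8,0.5,8,0.62
salient,8,0.7,1,0.58
salient,8,0.7,2,0.62
salient,8,0.7,3,0.65
salient,8,0.7,4,0.68
salient,8,0.7,5,0.72
salient,8,0.7,6,0.75
salient,8,0.7,7,0.78
salient,8,0.7,8,0.82
cross,5,0.5,1,0.17
cross,5,0.5,2,-0.08
cross,5,0.5,3,0.06
cross,5,0.5,4,-0.04
cross,5,0.5,5,0.03
cross,5,0.7,1,0.23
cross,5,0.7,2,-0.12
cross,5,0.7,3,0.08
cross,5,0.7,4,-0.06
cross,5,0.7,5,0.05
cross,8,0.5,1,0.17
cross,8,0.5,2,-0.12
cross,8,0.5,3,0.09
cross,8,0.5,4,-0.07
cross,8,0.5,5,0.06
cross,8,0.5,6,-0.05
cross,8,0.5,7,0.04
cross,8,0.5,8,-0.03
cross,8,0.7,1,0.23
cross,8,0.7,2,-0.17
cross,8,0.7,3,0.13
cross,8,0.7,4,-0.1
cross,8,0.7,5,0.08
cross,8,0.7,6,-0.07
cross,8,0.7,7,0.06
cross,8,0.7,8,-0.04
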