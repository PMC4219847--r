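time_s,survivors_A,survivors_B
0,5,15
3600,4.6,14.2
7200,3.2,13.2
10800,1.8,12.8
14400,1.4,12.6
18000,1.4,12.6
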