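time_s,survivors_A,survivors_B
0,5,14
3600,4.6,13
7200,3.8,12.8
10800,3.2,11.8
14400,2.6,11.2
18000,2.2,10.6
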