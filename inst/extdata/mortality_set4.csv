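time_s,survivors_A,survivors_B
0,5,12
3600,5,10.2
7200,4.8,8.4
10800,3.2,6.2
14400,3,5.4
18000,2,3
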