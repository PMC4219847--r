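time_s,survivors_A,survivors_B
0,5,11
3600,5,10
7200,4.2,8.6
10800,3,6.4
14400,2,3.4
18000,1.2,2
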