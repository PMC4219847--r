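time_s,survivors_A,survivors_B
0,10,10
3600,9.4,8.8
7200,9.2,6.8
10800,8.2,5
14400,7.8,4.2
18000,7.6,3.6
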