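time_s,survivors_A,survivors_B
0,5,10
3600,5,9.4
7200,5,7.4
10800,4.8,6.2
14400,4.6,5.8
18000,4.2,4.4
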