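time_s,survivors_A,survivors_B
0,5,13
3600,5,12.6
7200,4.4,10.2
10800,3.8,7.6
14400,2.2,6.4
18000,1.8,3.4
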