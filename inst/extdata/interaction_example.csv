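time,nA,nB,nAB,nABB,nABBB
714,6,5,3,1,0
741,5,3,3,2,0
751,5,2,3,1,1
778,4,1,4,1,1
781,4,2,5,0,1
783,4,3,5,1,0
797,5,4,4,1,0
801,5,2,2,3,0
803,5,3,3,2,0
805,5,4,4,1,0
821,5,3,3,2,0
824,5,4,4,1,0
830,6,5,3,1,0
832,5,4,4,1,0
846,5,3,3,2,0
850,6,5,3,1,0
858,5,3,3,2,0
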