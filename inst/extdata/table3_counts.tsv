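protease	occ_down	occ_up
CTSD	1	9
KLK4	0	7
PCSK4	0	7
PCSK5	0	7
PCSK6	0	7
PCSK7	0	7
MMP-7	0	5
CTSK	0	3
MMP-26	0	3
MMP-20	2	3
MMP-1	1	2
MMP-13	10	4
MMP-9	10	6
MMP-2	4	1
MMP-3	4	1
MMP-8	5	2
MMP-12	4	2
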