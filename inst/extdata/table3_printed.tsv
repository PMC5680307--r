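protease	pct_freq	score
CTSD	80	9.65
KLK4	100	7.53
PCSK4	100	7.53
PCSK5	100	7.53
PCSK6	100	7.53
PCSK7	100	7.53
MMP-7	100	5.38
CTSK	100	3.23
MMP-26	100	3.23
MMP-20	20	1.60
MMP-1	33	1.51
MMP-13	-43	-12.05
MMP-9	-25	-7.57
MMP-2	-60	-6.36
MMP-3	-60	-6.36
MMP-8	-43	-6.02
MMP-12	-33	-3.89
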