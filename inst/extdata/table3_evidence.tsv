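protease	source	direction
CTSD	transcriptomics	increase
PCSK5	transcriptomics	inconclusive
PCSK6	transcriptomics	decrease
PCSK7	transcriptomics	inconclusive
MMP-7	transcriptomics	increase
CTSK	transcriptomics	increase
MMP-26	transcriptomics	decrease
MMP-1	transcriptomics	increase
MMP-13	transcriptomics	decrease
MMP-2	transcriptomics	increase
MMP-3	transcriptomics	increase
MMP-8	transcriptomics	decrease
CTSD	protein_expression	increase
MMP-7	protein_expression	increase
MMP-9	protein_expression	decrease
MMP-3	protein_expression	increase
MMP-13	protein_expression	no_change
MMP-2	protein_expression	no_change
MMP-8	protein_expression	no_change
MMP-12	protein_expression	no_change
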