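# DSG2 positivity by disease stage, reconstructed from the reported
# percentages: 39% DSG2+ of n = 46 primary (stage I/II) tumors -> 0.39*46 =
# 17.94 -> 18 positive, 28 negative; 24% DSG2+ of n = 25 metastatic (stage
# III/IV) tumors -> 0.24*25 = 6 positive, 19 negative.  The reconstructed
# table reproduces the reported two-sided Fisher p = 0.294.
cohort	dsg2_pos	dsg2_neg
primary	18	28
metastatic	6	19
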