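# DSG2-positive tumor counts among multiple metastases collected at rapid
# autopsy from three patients: one uniformly positive (6/6), the other two
# 5/6 and 2/5.
patient_id	n_positive	n_total
A1	6	6
A2	5	6
A3	2	5
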