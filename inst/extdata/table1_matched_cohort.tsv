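# Matched primary/metastasis DSG2 immunofluorescence status for 8 patients
# with sequentially collected tumors.
patient_id	primary_status	metastasis_status	metastasis_site
1	-	-	lymph node
2	-	-	lymph node
3	-	+	dermis
4	+	+	lung
5	+	-	lymph node
6	+	+	lymph node
7	+	+	soft tissue
8	+	+	lymph node
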