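te_name	te_class	direction	sequence	product_length
Ltr80	DNA	F	AGTTCCAGGGAGCTATGCTGGGT	431
Ltr80	DNA	R	CGATGCCTCACGTCCAAAGAC	431
Tcl5	DNA	F	GGACAACCATCTCTGCAGCAC	231
Tcl5	DNA	R	GATGAGCAGTGCCTGGTTTCC	231
Tcl7	DNA	F	GGTGTTTCAGATTCATGCAGCGA	496
Tcl7	DNA	R	GTGCTGTCCAAAACAAGCAGTGC	496
Tcl3	DNA	F	CCCTTTACTTTCAGTGCAGCA	296
Tcl3	DNA	R	TTGCACAGTGCTCCTTGGGA	296
hAT1	DNA	F	CACAGATGGAGCCCCTGCTA	321
hAT1	DNA	R	CCTCCTGATGGACCAAAAGC	321
hAT3	DNA	F	AAGAGCAACACGGATCAGATGC	456
hAT3	DNA	R	CATTGAGAAGCCAATGGTGC	456
hAT5	DNA	F	ACGTTGTGTTGATGTAGCTTGGT	296
hAT5	DNA	R	CCCTCCAAAAGGCTGTTCTC	296
Gyp37_12	RNA	F	CCTCCTAGGCTTCCGTAGTT	346
Gyp37_12	RNA	R	AACACAGACGGTGCCTTCTG	346
Gyp13_5	RNA	F	CTGTGGCAGGAGCAGTCCATCTT	296
Gyp13_5	RNA	R	CTTTGACCCGTTGGCACTCAAGG	296
Gyp13_10	RNA	F	GGGTGAGTTCTGGAAAACCAGC	461
Gyp13_10	RNA	R	GCGCTCATTAGTGGCCATGAGTG	461
Gyp9_3F	RNA	F	ACCCAAATAGCTGTCCGCTT	260
Gyp9_3F	RNA	R	CAGTGCGTATCTTCGGGAACC	260
Gyp9_4	RNA	F	GTTCCCGAAGGTACGCACTG	421
Gyp9_4	RNA	R	TGGAGAGGTACGTTAGCCCCA	421
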