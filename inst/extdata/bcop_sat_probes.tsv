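# Published FISH oligo probe set for Bradysia coprophila satellite DNA
# families (core-chromosome families and L-chromosome-enriched families).
family	variant	unit_len	probe_seq
BcopSat-145	A	145	GGGTCCTCGGACTAAGGCCGCTACTAGGGCCCTATGTGT
BcopSat-145	B	145	GGGCCCTTGGACTAAGGCCGCTACTCGGCCCTAAGTGT
BcopSat-155	.	155	ACTGCGCACCGTTGAAACACACTAAAAACTCACTTGCCT
BcopSat-176	A	176	AGCATAGGCTTAGCATACATTTTCTTAATAATT
BcopSat-176	B	176	CAAGCATAGGCGTAGCAAACATTTTCTTAATA
BcopSat-37	A	37	AAAATAATTAATTTAAACGTCGAAATTCGTCATTTGG
BcopSat-37	B	37	AAAATAATTAATTTAAACGTCGAATTTCATCGTTTGG
BcopSat-109	.	109	GGAAGTTAGGAAGTGCCAGAGGAATCATCTGTCAT
BcopSat-162	.	162	GCCATACATTATGACCAAAAAATGGCATTGTT
BcopSat-129	.	129	GTCACTCACACACAAAAGCGTACACTGTGGTCAC
BcopSat-94	.	94	TCGGTCTCTTACATTCTCGTAAAATATTCAAAA
BcopSat-10	.	10	AAAACGTATTAAAACGTATTAAAACGTATT
BcopSat-38	.	38	AAAAATTTGGTCACTTTCGGTGTATGTTGGGCAGCGGG
BcopSat-39	.	39	AAAATTTGGTCACTTTCAGGGTTTGGTTGGGCAGCTGT
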