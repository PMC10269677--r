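gene_id	log2fc
orf4757	6.24
orf4758	4.48
orf488	-4.24
orf492	-2.17
orf494	-2.43
orf495	-1.76
orf496	-1.76
orf497	-1.94
orf3562	-4.30
orf1359	1.93
orf2787	3.19
orf961	-3.46
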