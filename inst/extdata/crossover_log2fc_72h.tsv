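gene_id	log2fc
orf4757	6.19
orf4758	5.01
orf488	-2.30
orf492	-1.92
orf494	-2.61
orf495	-2.86
orf496	-2.27
orf497	-1.85
orf3562	-3.83
orf1359	-1.18
orf2787	1.21
orf961	1.17
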