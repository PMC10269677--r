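gene_id	log2fc
orf4757	6.06
orf4758	4.72
orf488	-1.26
orf492	-1.33
orf494	-2.07
orf495	-2.41
orf496	-2.15
orf497	-1.80
orf3562	-2.43
orf1359	-2.08
orf2787	-2.85
orf961	-1.48
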