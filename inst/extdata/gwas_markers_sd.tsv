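marker	chrom	pos	maf	effect
SNP6421	chrom02	14565718	0.10	-1.00
SNP30209	chrom05	75998329	0.17	0.54
SNP43760	chrom08	26946649	0.45	0.84
SNP92152	chrom15	50878458	0.29	0.43
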