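name	file	type	md5	note
synthetic-profiles	synthetic-profiles.tsv	profiles	13e48cd9e782a2d7868352a5e3f3f532	synthetic clonal population (simulate_population, spec: 6 singletons + complexes of 5 and 2 STs, seed 20260919); no real-strain data
synthetic-alleles	synthetic-alleles.fasta	alleles	71925fa281099ac7423201f2f42ece69	allele library of the same synthetic population; headers locus_allele
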