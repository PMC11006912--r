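#build=EquCab3.0-synthetic
entry_id	phenotype	category	chrom	pos	ref	alt
syn_gbed	GBED-like	disease_trait_causing	26	1000	G	A
syn_myhm	MYHM-like	disease_trait_causing	26	2000	C	T
syn_gait	gait-like	trait_associated	26	3000	A	G
syn_coat1	coat-dilution	coat_color	26	4000	G	A
syn_coat2	coat-white	coat_color	26	5000	C	T
syn_assoc1	myopathy-assoc	disease_associated	26	6000	T	C
syn_assoc2	fracture-assoc	disease_associated	26	7000	A	G
syn_trait1	height-assoc	trait_associated	26	8000	G	T
syn_trait2	gait-assoc	trait_associated	26	9000	CTTG	C
syn_absent	never-observed	disease_trait_causing	26	10000	T	G
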