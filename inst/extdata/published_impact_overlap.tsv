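snpeff_impact	vep_impact	count
HIGH	HIGH	25550
HIGH	MODERATE	336
HIGH	LOW	392
MODERATE	HIGH	58
MODERATE	MODERATE	179480
MODERATE	LOW	2000
LOW	HIGH	17
LOW	MODERATE	64
LOW	LOW	358514
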