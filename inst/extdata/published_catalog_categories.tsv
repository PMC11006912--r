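category	n_catalog	n_detected	median_vf_pct	vf_iqr_low_pct	vf_iqr_high_pct
disease_trait_causing	36	21	0.33	0.16	0.58
coat_color	62	24	2.60	0.64	10.60
disease_associated	73	67	16.40	5.80	43.80
trait_associated	10	10	13.15	5.58	31.65
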