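entry_id	lethal_homozygote	expected_breeds
syn_gbed	TRUE	Quarter Horse
syn_myhm	FALSE	Quarter Horse
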