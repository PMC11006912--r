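breed	ne	source
Arabian	470	array54K
Belgian	160	array54K
Clydesdale	120	array54K
Franches-Montagnes	180	array54K
Icelandic	490	array54K
Morgan	250	array54K
Quarter Horse	310	array54K
Shetland	200	array54K
Standardbred	150	array54K
Thoroughbred	100	array54K
Arabian	430	array2M
Belgian	170	array2M
Franches-Montagnes	190	array2M
Icelandic	520	array2M
Morgan	260	array2M
Quarter Horse	330	array2M
Standardbred	140	array2M
Thoroughbred	110	array2M
Welsh Pony	220	array2M
Shetland	210	array2M
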