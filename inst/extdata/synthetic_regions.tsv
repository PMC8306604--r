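# Synthetic example tip-to-region map (not real samples).
# Aru is classified as Wallacean despite its Sahul-shelf past.
tip_label	region
Aru1	WLC
Aru2	WLC
Seram1	WLC
Seram2	WLC
Kei1	WLC
Kei2	WLC
Keerom1	PAP
Keerom2	PAP
Mappi1	PAP
Mappi2	PAP
Cairns1	AUS
Cairns2	AUS
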