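id	display_name	entity_class
TCDD	TCDD	compound
PCB153	PCB 153	compound
ppDDE	p,p'-DDE	compound
AhR	AhR (AhR/ARNT complex)	receptor
PXR	PXR	receptor
AR	AR	receptor
CREB1	CREB1	transcription_factor
RelA	RelA (p65)	transcription_factor
c-Jun	c-Jun	transcription_factor
IL-8	IL-8	cytokine
IL-6	IL-6	cytokine
TNFa	TNF-alpha	cytokine
fetuinA	fetuin A	lipoprotein
cyclinD1	cyclin D1	generic_protein
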