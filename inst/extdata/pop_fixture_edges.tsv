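source	target	effect	mechanism	trust	directness	provenance
TCDD	AhR	activation	binding	high	direct	fixture
PCB153	PXR	inhibition	binding	high	direct	fixture
ppDDE	AR	inhibition	binding	high	direct	fixture
AhR	IL-8	activation	transcription regulation	high	direct	fixture
AhR	IL-6	activation	transcription regulation	high	direct	fixture
AhR	RelA	activation	binding	high	direct	fixture
AhR	cyclinD1	activation	transcription regulation	high	direct	fixture
PXR	CREB1	inhibition	binding	high	direct	fixture
PXR	RelA	inhibition	binding	high	direct	fixture
PXR	TNFa	inhibition	transcription regulation	high	direct	fixture
AR	IL-8	inhibition	transcription regulation	high	direct	fixture
AR	IL-6	inhibition	transcription regulation	high	direct	fixture
AR	RelA	inhibition	binding	high	direct	fixture
AR	c-Jun	inhibition	binding	high	direct	fixture
AR	cyclinD1	inhibition	transcription regulation	high	direct	fixture
CREB1	IL-8	activation	promoter binding	high	direct	fixture
CREB1	IL-6	activation	promoter binding	high	direct	fixture
CREB1	cyclinD1	activation	promoter binding	high	direct	fixture
RelA	IL-6	activation	transcription regulation	high	direct	fixture
RelA	TNFa	activation	transcription regulation	high	direct	fixture
RelA	fetuinA	activation	transcription regulation	high	direct	fixture
c-Jun	TNFa	activation	transcription regulation	high	direct	fixture
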