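CLN03	activates	SWI04
CLN03	activates	SWI06
CLN03	activates	MBP01
CDC28	activates	MBP01
CDC28	activates	SWI04
CDC28	activates	SWI06
CDC28	activates	CDC06
CDC28	represses	SIC01
SWI04	activates	CLN01
SWI04	activates	CLN02
SWI04	activates	CDC28
SWI06	activates	CLB05
SWI06	activates	CLB06
SWI06	activates	CLN01
SWI06	activates	CLN02
SWI06	activates	CDC28
MBP01	activates	CLB05
MBP01	activates	CLB06
MBP01	activates	CDC28
CLN01	activates	SWI06
CLN01	activates	SWI04
CLN01	represses	SIC01
CLN02	represses	SIC01
CLN02	activates	SWI04
CLN02	activates	SWI06
SIC01	represses	CDC28
SIC01	represses	CLB05
SIC01	represses	CLB06
CDC20	represses	CLB05
CDC20	represses	CLB06
CDC20	represses	CDC28
CLB05	activates	CDC06
CLB06	activates	CDC06
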