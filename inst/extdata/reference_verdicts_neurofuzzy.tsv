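source	target	sign	verdict
CLN03	SWI04	activator	Consistent
CLN03	SWI06	activator	NotFound
CLN03	MBP01	activator	NotFound
CDC28	MBP01	activator	Consistent
CDC28	SWI04	activator	Consistent
CDC28	SWI06	activator	NotFound
CDC28	CDC06	activator	NotFound
CDC28	SIC01	repressor	NotFound
SWI04	CLN01	activator	NotFound
SWI04	CLN02	activator	NotFound
SWI04	CDC28	activator	NotFound
SWI06	CLB05	activator	Consistent
SWI06	CLB06	activator	Consistent
SWI06	CLN01	activator	Inconsistent
SWI06	CLN02	activator	Consistent
SWI06	CDC28	activator	Consistent
MBP01	CLB05	activator	NotFound
MBP01	CLB06	activator	Consistent
MBP01	CDC28	activator	NotFound
CLN01	SWI06	activator	Consistent
CLN01	SWI04	activator	Consistent
CLN01	SIC01	repressor	Inconsistent
CLN02	SIC01	repressor	NotFound
CLN02	SWI04	activator	Consistent
CLN02	SWI06	activator	NotFound
SIC01	CDC28	repressor	NotFound
SIC01	CLB05	repressor	NotFound
SIC01	CLB06	repressor	NotFound
CDC20	CLB05	repressor	Consistent
CDC20	CLB06	repressor	Inconsistent
CDC20	CDC28	repressor	Consistent
CLB05	CDC06	activator	NotFound
CLB06	CDC06	activator	NotFound
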