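element	anc	der	region
CsuPLE1.1	AG	GA	inside_orf
CsuPLE1.1	GT	AA	outside_orf
Csu-Ty3	AA	TT	inside_orf
Csu-Ty3	GA	TC	inside_orf
Csu-Ty3	CG	GA	inside_orf
Csu-Ty3	AT	TA	inside_orf
Csu-Ty3	AT	CC	inside_orf
Csu-Ty3	ACA	TTG	inside_orf
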