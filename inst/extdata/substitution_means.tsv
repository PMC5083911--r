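element	category	mean	se
CsuPLE1.1	transition	44.5	3.52
CsuPLE1.1	transversion	18.25	1.44
CsuPLE1.1	A>G	15.75	1.7
CsuPLE1.1	G>A	7.25	0.95
CsuPLE1.1	T>C	14.5	1.32
CsuPLE1.1	C>T	7	1.58
Csu-Ty3	transition	51.75	6.63
Csu-Ty3	transversion	24.5	1.66
Csu-Ty3	A>G	17.75	2.78
Csu-Ty3	G>A	10.25	1.25
Csu-Ty3	T>C	15.5	2.53
Csu-Ty3	C>T	8.25	0.48
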