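protein	orf_bp	length_aa	mw_kda	pi
CruCA1	1032	356	40.89	8.47
CruCA2	969	322	36.90	9.63
CruCA3	789	262	29.04	5.88
CruCA4	855	284	32.86	9.42
CruCA5	1008	335	36.06	8.77
CruCA6	846	281	32.06	8.26
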