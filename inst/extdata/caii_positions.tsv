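role	caii_pos	expected_residue
triad_1	94	H
triad_2	96	H
triad_3	119	H
proton_shuttle	64	H
gatekeeper_glu	106	E
gatekeeper_thr	199	T
bridge_canonical_1	23	A
bridge_canonical_2	203	L
bridge_cnidarian_1	99	S
bridge_cnidarian_2	227	K
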