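gene	position	ref	alt	label
LEP	-38	G	A	LEP_-38a
LEP	-30	A	T	LEP_-30t
LEP	-35	A	G	LEP_-35g
GCG	-41	A	G	GCG_-41g
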