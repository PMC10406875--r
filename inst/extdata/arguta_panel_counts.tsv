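marker	sex	subpopulation	presence	absence
P51	female	F1	2	50
P51	female	wild	1	12
P51	male	F1	45	0
P51	male	wild	17	1
P11	female	F1	2	50
P11	female	wild	2	11
P11	male	F1	45	0
P11	male	wild	17	1
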