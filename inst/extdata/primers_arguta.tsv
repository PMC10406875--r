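name	forward	reverse	annealing_temp	expected_size
P51	TCTTCCTCTTGGTGCCCG	TCAAAGAACCGCTAATCCCAT	60	609
P11	TCTCGCCATCTTCAACCATTT	ATCTTGGCGTATCTCGGCTTT	65	304
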