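name	role	sequence
target_1	target_dna	AAAGAGATGCAGAGTCCTC
target_2	target_dna	GAGATGCAGAGTCCTCAGA
target_3	target_dna	AAGAGATGCAGAGTCCTCA
duplex_sense	sense_strand	A*A*A*GAGAUGCAGAGUC*C*U*CTT
duplex_antisense	antisense_strand	G*A*G*GACUCUGCAUCUC*U*U*UTT
scrambled_sense	sense_strand	U*U*C*UCCGAACGUGUCA*C*G*UTT
scrambled_antisense	antisense_strand	A*C*G*UGACACGUUCGGA*G*A*ATT
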