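study	sample_size	n_female
SOL	11986	7026
BioMe	10727	6766
WHI	5386	5386
MEC	7772	3555
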