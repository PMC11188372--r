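mie	n_targets	n_mapped
TF01	5	5
TF02	4	4
TF03	7	7
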