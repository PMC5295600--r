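group_category	no_te	te
hrta_groups	976	436
other_groups	2572	1436
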