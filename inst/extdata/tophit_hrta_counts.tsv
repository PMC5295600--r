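kind	hrta	other
map_snp	950	3340
psv	462	668
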