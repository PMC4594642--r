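# near-zero rearrangement regime: long unchanged lineages
fusion_rate = 0.02
fission_rate = 0.02
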