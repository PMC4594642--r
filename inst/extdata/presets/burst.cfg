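# rapid repatterning regime: ~6 events/myr split between fusions and fissions
fusion_rate = 3
fission_rate = 3
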