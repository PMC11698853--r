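rot_diffusivity: 0.0592176
circ_frequency: 0
episodes_per_cycle: 300
n_cycles: 40
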