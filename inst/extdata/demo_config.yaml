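mosaic_extent_deg: 0.25
n_starts: 64.0
defocus_D: 0.067
sessions: 3.0
noise_frac: 0.1

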