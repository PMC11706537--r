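# Example configuration for `isofusion synth` (keys mirror synth_config()).
n_genes: 60
n_terms: 4
e: 12
s: 16
n_latent: 4
signal: 3
noise_sd: 1
iii_density: 0.8
homolog_frac: 0.1
seed: 7
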