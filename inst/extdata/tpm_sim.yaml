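# Example TPM-simulation config: a small tissue atlas with one planted
# co-expression module peaking in the stigma-like sample.
n_genes: 500
sample_labels:
  - flower_st9
  - flower_st11
  - flower_st12
  - flower_st14
  - carpel
  - stigma
  - ovules
  - anther
noise_sd: 0.05
zero_fraction: 0.1
bg_meanlog: 1.0
bg_sdlog: 1.5
seed: 1
modules:
  - size: 10
    shape: peak
    peak_at: 6        # stigma-peak archetype
  - size: 8
    shape: decreasing
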