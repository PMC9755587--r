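# Example plate-simulation config: the canonical 5 tissues x 3 biological x 3
# technical design with three reference genes and one target.
sample_labels: [pistil_st11, pistil_st12, anther_st12, pistil_st14, silique_st17]
calibrator: anther_st12
n_bio: 3
n_tech: 3
cq_noise_sd: 0.1
bio_noise_sd: 0.5
seed: 7
ref_base_cq: {RCE1: 22.0, TUA2: 23.0, YLS8: 24.0}
target_base_cq: {TARGET1: 26.0}
targets:
  TARGET1:
    pistil_st11: 0.25
    pistil_st12: 0.5
    anther_st12: 1.0
    pistil_st14: 2.0
    silique_st17: 4.0
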