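{
  "G": 50,
  "gene_length": 400,
  "depth_meanlog": 5.3,
  "depth_sdlog": 1.5,
  "de_fraction": 0.05,
  "de_p": 0.6,
  "theta_model": {"variant": "primer_free", "D": 1, "gamma": -0.8},
  "seed": 101
}
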