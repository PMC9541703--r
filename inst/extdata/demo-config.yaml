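# Packaged demo: the standard synthetic two-trait study, end to end.
seed: 1
analyses:
  demo:
    simulate:
      M: 100000
      n_blocks: 1000
      rho_block: 0.8
      pis: [0.90, 0.03, 0.03, 0.04]
      sigma_b2_1: 2.0e-4
      sigma_b2_2: 2.0e-4
      rho12: 0.6
      N1: 100000
      N2: 100000
      seed: 1
fdr:
  n_prune_iter: 20
  prune_r2: 0.1
replication:
  trait: 1
  n_rep: 50000
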