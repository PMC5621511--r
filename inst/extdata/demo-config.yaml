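# Demo pipeline configuration: a small synthetic world pushed through every
# stage. Paths for the biogeo stage point at files shipped with the package;
# replace them (and out_dir) for real runs.
stages: [simulate, richness, hotspot, nestedness, cooccur, envmodel, biogeo]
out_dir: macrorich-demo-run
simulate:
  seed: 101
  shape: [15, 15]
  n_species: 30
  decay: 4
  noise_sd: 0.05
hotspot:
  weights: queen
  alpha: 0.05
  correction: fdr
nestedness:
  seed: 102
  iters: 500
  indices: [T, BR, NODF]
cooccur:
  seed: 103
  nulls: 1000
envmodel:
  seed: 104
  energy: PET
  quantiles: [0.01, 0.99]
  boot: 1000
biogeo:
  seed: 105
  maps: 100
  tree: demo-tree.nwk
  coding: demo-coding.csv
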