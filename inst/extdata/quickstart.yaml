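# Reduced desk-scale pipeline configuration: one tree count, three minimum
# leaf sizes.  Usable via read_run_config() or `ivforest run --config ...`.
synthetic:
  n_patients: 8000
  n_areas: 150
  seed: 7
num_trees: 200
min_leaf_sizes: [100, 200, 400]
alpha: 0.05
out_dir: ivforest_run
seed: 7
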