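# Demo experiment: clustered producers vs uniform non-producers, small
# ensemble for a quick end-to-end comparison run.
icc:
  kind: icc2
simulation:
  t_end: 200
  n_record: 9
  n_reps: 10
estimator:
  grid_n: 256
solver:
  k_nodes: 257
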