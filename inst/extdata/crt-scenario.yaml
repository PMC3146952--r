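# Simple cluster-randomized trial: sanitation mobilization vs control,
# HAZ outcome, variance components fitted from a two-level training cohort.
design:
  arms: 2
  clusters_per_arm: 100
  units_per_cluster: 10
  timepoints: 1
  cluster_treatments: [A]
params:
  family: continuous
  mu: -0.875
  beta1: 0.2
  sigma_g: 0.482
  sigma_e: 1.297
run:
  alpha: 0.05
  n_reps: 10000
  seed: 42
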