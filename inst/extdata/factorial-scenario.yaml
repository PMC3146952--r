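# Two-treatment factorial: sanitation randomized across villages, LNS to
# half the households within each village; baseline + follow-up HAZ with
# 10% dropout. Variance components fitted from a three-level longitudinal
# training cohort.
design:
  arms: 2
  clusters_per_arm: 60
  units_per_cluster: 20
  timepoints: 2
  cluster_treatments: [A]
  unit_treatments: [X]
  unit_allocation_fraction: 0.5
  dropout_rate: 0.1
params:
  family: factorial
  mu: -1.98
  beta1: 0.15
  beta2: 0.15
  beta3: 0.15
  sigma_v: 0.297
  sigma_c: 1.259
  sigma_e: 1.079
run:
  alpha: 0.05
  n_reps: 10000
  seed: 42
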