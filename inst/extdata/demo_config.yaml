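# Demonstration run: simulated mixed cohort, full clinical-panel profiling.
# note: "n" must be quoted -- bare `n` is YAML 1.1 shorthand for false
simulate:
  scenario: demo
  "n": 2000
  seed: 5
panels:
  clinical: [lipid, electrolyte, static, null01]
preprocess:
  log_phenotypes: []
stages: [preprocess, sexdiff, changepoint, variance, cluster]
changepoint:
  phenotypes: [electrolyte]
  min_n: 30
variance:
  features: [lipid, electrolyte]
  folds: 5
  repeats: 2
  n_clusters: 2
seed: 1
k: 8
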