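# Example pipeline configuration for run_pipeline().
# Stages run in order; every stage derives its randomness from `seed`.
seed: 7
out_dir: runs/demo
stages: [simulate, fit, compare, recover, linkage, neural]

simulate:
  n: 20          # participants
  study: "2a"    # 2a (48 trials), 2b (56, varying efficiency), fmri (48, forced)

# To analyze an existing table instead of simulating, drop "simulate" from
# stages and point `data.path` at a CSV; map its headers to the canonical
# names and recode condition labels here.
# data:
#   path: study2.csv
#   column_map:
#     d_a: cost
#     d_b: repayment
#   condition_recode:
#     impossible: repayment_impossible
#     possible: repayment_possible

fit:
  models: ["1.1", "1.7", "1.8"]

recover:
  model: "1.1"
  n: 20
  study: "2a"

neural:
  n: 20
  v: 200
  snr: 0.11
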