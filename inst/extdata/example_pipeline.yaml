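# Example pipeline configuration for run_pipeline().
# Keys mirror pipeline_config() / sim_config(); unknown keys are rejected.
seed: 7
n_ref: 60
k_pcs: 3
f3_blocks: 40
uniparental_R: 1000
date_ancestry: Malay
date_model: one_date
sim:
  n_samples: 60
  n_snps: 500
  g: 6.55
  maternal_props: {Chinese: 0.87, Malay: 0.12, Indian: 0.01}
  paternal_props: {Chinese: 0.95, Malay: 0.05, Indian: 0.00}
  sex_ratio: 0.35
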