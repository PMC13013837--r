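# Default synthetic TFAP pipeline configuration.
# One root seed; every stochastic component derives a child seed from it.
seed: 1
out_dir: tfap_run

stages:
  simulate: true
  quantify: true
  profile: true
  behavior: true
  de: true
  regulon: true
  integrate: true

simulate:
  n_tfs: 30
  n_genes: 1000
  n_drivers: 2
  n_animals_per_group: 10
  groups: [control, susceptible]
  battery_size: 6          # at most six reporter constructs per animal
  regulon_size: 30
  effect_log2fc: 0.5       # driver activity shift in non-control groups
  regulon_weight: 1.0
  noise_sd_reporter: 0.1   # log2-scale multiplicative reporter noise
  noise_sd_expr: 0.25      # log2-scale expression noise
  noise_sd_behavior: 0.15  # additive SI-rate noise
  promoter_upstream: 1000
  promoter_downstream: 200

behavior:
  si_direction: with_over_without
  outlier_threshold: 4     # exclude SI-rate strictly larger than 4

de:
  contrast_group: susceptible
  pseudocount: 1
  p_thresh: 0.05
  fc_up: 2
  fc_down: 0.5
  use_q: false             # printed DEG rule gates on raw p

regulon:
  threshold_policy: fraction
  threshold: 0.8           # of each motif's maximum log-odds score

integrate:
  use_true_regulons: false
  discordance_factor: 0.25
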