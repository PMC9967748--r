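# Example pipeline configuration. Any key omitted falls back to the
# defaults in default_pipeline_config(); unknown keys are an error.
seed: 7

decontam:
  slope_margin: 0.1      # zero-slope band half-width, boundary inclusive
  min_prevalence: 0.1    # fraction of samples a taxon must appear in (floor 3)
  slope_scale: log       # or raw
  plate_share: 0.9       # top-2-plate read share that flags a taxon
  max_plates: 2
  date_share: 0.9        # single-date read share that flags a taxon

da:
  p_threshold: 0.05
  lfc_threshold: 1       # |log2 fold change| gate
  adjust: true           # apply p_threshold to Bonferroni-adjusted p

clinical:
  p_threshold: 0.05
  collapse_stage: true   # Stage IVA -> IV, T1b -> T1, ...

enrichment:
  n_perm: 1000
  weight: 1              # hit-weight exponent of the running sum
  metric: pearson        # or spearman
  p_threshold: 0.05
  fdr_threshold: 0.25

simulate:
  n_tumor: 453
  n_normal: 54
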