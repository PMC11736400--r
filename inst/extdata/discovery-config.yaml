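# Example end-to-end discovery configuration (see ?default_config).
# Any omitted key falls back to the package default.
data:
  source: synthetic
  n_primary: 24
  n_metastatic: 12
  n_control: 13
  n_replicates: 2
  n_proteins: 257
  n_metabolites: 88
  n_immunoglobulin_decoys: 15
  marker_effects: default
  mcar_rate: 0.02
  mnar_slope: 1.0
  replicate_cv: 0.15
  age_marker_rho: 0.34
  seed: 1
preprocess:
  max_missing: 0.4
  remove_immunoglobulins: true
  impute_trees: 100
  impute_max_iter: 10
differential:
  p_threshold: 0.05
  adjust: none
selection:
  k_values: [1, 3, 5, 7, 9]
  n_max: 10
  cv_mode: loso        # leave-one-subject-out; "loo" treats replicates as independent
  lasso_rule: min
  lasso_folds: 10
  forest_trees: 500
  top_fraction: 0.1
evaluation:
  linkage: complete
  max_candidates: 8
  max_subset_size: 4
  protein_level: replicate   # matches the duplicate-as-independent convention
  metabolite_level: subject  # duplicates averaged to one value per subject
  combined_level: subject
integration:
  k_partitions: 6
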