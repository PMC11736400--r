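# Orchestration: configuration, seeded end-to-end discovery runs, stage
# logging, machine-readable run report.

#' Default discovery configuration
#'
#' Nested list mirroring the YAML configuration schema, with the study's
#' cohort shape and the documented analysis defaults: per-observation
#' median centring in log2 space, leave-one-subject-out cross-validation,
#' complete linkage, replicate-level evaluation for proteomics and
#' subject-level evaluation for metabolomics and combined signatures.
#'
#' @param seed Integer seed governing all stochastic stages.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    data = list(source = "synthetic", n_primary = 24, n_metastatic = 12,
                n_control = 13, n_replicates = 2, n_proteins = 257,
                n_metabolites = 88, n_immunoglobulin_decoys = 15,
                marker_effects = "default", mcar_rate = 0.02, mnar_slope = 1,
                replicate_cv = 0.15, age_marker_rho = 0.34, seed = seed),
    preprocess = list(max_missing = 0.4, remove_immunoglobulins = TRUE,
                      impute_trees = 100, impute_max_iter = 10),
    differential = list(p_threshold = 0.05, adjust = "none"),
    selection = list(k_values = c(1, 3, 5, 7, 9), n_max = 10,
                     cv_mode = "loso", lasso_rule = "min", lasso_folds = 10,
                     forest_trees = 500, top_fraction = 0.1),
    evaluation = list(linkage = "complete", max_candidates = 8,
                      max_subset_size = 4, protein_level = "replicate",
                      metabolite_level = "subject", combined_level = "subject"),
    integration = list(k_partitions = 6),
    output = list(dir = NULL)
  )
}

CONFIG_RANGES <- list(
  "data.mcar_rate" = c(0, 1),
  "data.mnar_slope" = c(0, Inf),
  "data.replicate_cv" = c(0, Inf),
  "data.age_marker_rho" = c(-1, 1),
  "preprocess.max_missing" = c(0, 1),
  "selection.top_fraction" = c(1e-12, 1),
  "differential.p_threshold" = c(0, 1),
  "evaluation.max_candidates" = c(1, 12),
  "evaluation.max_subset_size" = c(1, 12),
  "integration.k_partitions" = c(1, Inf)
)

#' Validate a discovery configuration
#'
#' Schema check without running anything: unknown sections or keys, missing
#' required keys, range violations.
#'
#' @param config Path to a YAML configuration or a nested list.
#' @return Character vector of findings (empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  ref <- default_config()
  findings <- character()
  unknown_sections <- setdiff(names(config), names(ref))
  if (length(unknown_sections))
    findings <- c(findings, paste0("unknown section: ", unknown_sections))
  for (sec in intersect(names(config), names(ref))) {
    unknown <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    extra_ok <- if (sec == "data")
      c("protein_groups", "metabolites", "sample_sheet") else character()
    unknown <- setdiff(unknown, extra_ok)
    if (length(unknown))
      findings <- c(findings, paste0("unknown key: ", sec, ".", unknown))
  }
  dat <- config$data
  if (!is.null(dat) && identical(dat$source %||% "synthetic", "synthetic")) {
    req <- c("n_primary", "n_metastatic", "n_control")
    miss <- req[!req %in% names(dat)]
    if (length(miss))
      findings <- c(findings, paste0("missing required key: data.", miss))
  }
  flat <- function(x, prefix = NULL) {
    out <- list()
    for (nm in names(x)) {
      key <- paste(c(prefix, nm), collapse = ".")
      if (is.list(x[[nm]]) && !is.data.frame(x[[nm]]))
        out <- c(out, flat(x[[nm]], key))
      else out[[key]] <- x[[nm]]
    }
    out
  }
  fx <- flat(config)
  for (key in intersect(names(fx), names(CONFIG_RANGES))) {
    v <- fx[[key]]
    rng <- CONFIG_RANGES[[key]]
    if (is.numeric(v) && (any(v < rng[1]) || any(v > rng[2])))
      findings <- c(findings,
                    sprintf("range violation: %s = %s outside [%s, %s]",
                            key, paste(v, collapse = ","), rng[1], rng[2]))
  }
  findings
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: merge user config over defaults (shallow per section)
merge_config <- function(config) {
  ref <- default_config()
  for (sec in names(ref)) {
    user <- config[[sec]] %||% list()
    for (key in names(user)) ref[[sec]][[key]] <- user[[key]]
  }
  ref
}

#' Candidate panel for the grid search
#'
#' The strict consensus features; when empty, the lenient union of pairwise
#' intersections; when that is empty too, the top features by
#' differential-abundance p-value. Capped at `max_candidates`.
#'
#' @param cons A [consensus()] signature.
#' @param de A [moderated_t_test()] table used as fallback ranking.
#' @param max_candidates Cap on the panel size (grid search accepts <= 12).
#' @return Character vector of feature ids.
#' @export
select_candidates <- function(cons, de, max_candidates) {
  feats <- cons$features
  if (!length(feats)) feats <- cons$lenient
  if (!length(feats)) feats <- de$feature_id[order(de$p_value)]
  utils::head(feats, max_candidates)
}

eval_to_list <- function(ev) {
  list(features = ev$features, n = ev$n, confusion = as.list(ev$confusion),
       accuracy = ev$accuracy, ci_low = ev$ci_low, ci_high = ev$ci_high,
       nir = ev$nir, p_acc_gt_nir = ev$p_acc_gt_nir,
       sensitivity = ev$sensitivity, specificity = ev$specificity,
       level = ev$level, contrast = ev$contrast, linkage = ev$linkage)
}

#' Run the end-to-end discovery pipeline
#'
#' Generates (or ingests) a cohort, preprocesses each omic, and for both
#' study contrasts runs differential abundance, the three selection
#' algorithms, consensus, grid-searched signature evaluation, multi-omic
#' integration and similarity-matrix partitioning. All stochastic stages
#' derive from the single seed; reports contain no timestamps, so identical
#' config + seed gives byte-identical artifacts.
#'
#' @param config Path to a YAML configuration, or a nested list (see
#'   [default_config()]); partial configurations are completed with the
#'   defaults.
#' @param seed Optional seed overriding `config$data$seed`.
#' @param outdir Optional output directory; when given, writes
#'   `report.json`, `tables/*.tsv`, `signatures/*.json` and `log.txt`.
#' @return The run report (nested list, class `ev_run_report`), invisibly
#'   when `outdir` is given.
#' @export
run_discovery <- function(config = default_config(), seed = NULL,
                          outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  findings <- validate_config(config)
  if (length(findings))
    stop("invalid configuration:\n  ", paste(findings, collapse = "\n  "),
         call. = FALSE)
  cfg <- merge_config(config)
  if (!is.null(seed)) cfg$data$seed <- seed
  seed <- cfg$data$seed
  log_lines <- c(sprintf("evsig %s", as.character(utils::packageVersion("evsig"))),
                 sprintf("seed: %d", seed),
                 "normalisation: log2 + per-observation median centring",
                 sprintf("cv_mode: %s", cfg$selection$cv_mode),
                 sprintf("linkage: %s", cfg$evaluation$linkage),
                 sprintf("evaluation levels: protein=%s metabolite=%s combined=%s",
                         cfg$evaluation$protein_level,
                         cfg$evaluation$metabolite_level,
                         cfg$evaluation$combined_level))

  # --- data ---------------------------------------------------------------
  if (identical(cfg$data$source, "files")) {
    proteins <- read_maxquant_protein_groups(cfg$data$protein_groups)
    metabolites <- read_feature_table(cfg$data$metabolites)
    sheet <- read_sample_sheet(cfg$data$sample_sheet)
    truth <- NULL
  } else {
    me <- cfg$data$marker_effects
    me <- if (identical(me, "none")) default_marker_effects()[0, ]
          else if (identical(me, "default") || is.null(me)) default_marker_effects()
          else as.data.frame(do.call(rbind, lapply(me, as.data.frame)))
    ccfg <- cohort_config(
      n_primary = cfg$data$n_primary, n_metastatic = cfg$data$n_metastatic,
      n_control = cfg$data$n_control, n_replicates = cfg$data$n_replicates,
      n_proteins = cfg$data$n_proteins, n_metabolites = cfg$data$n_metabolites,
      n_immunoglobulin_decoys = cfg$data$n_immunoglobulin_decoys,
      marker_effects = me, mcar_rate = cfg$data$mcar_rate,
      mnar_slope = cfg$data$mnar_slope, replicate_cv = cfg$data$replicate_cv,
      age_marker_rho = cfg$data$age_marker_rho, seed = seed)
    cohort <- generate_cohort(ccfg)
    proteins <- cohort$proteins; metabolites <- cohort$metabolites
    sheet <- cohort$sheet; truth <- cohort$truth
  }
  log_lines <- c(log_lines, sprintf("observations: %d (subjects: %d)",
                                    nrow(proteins$values),
                                    length(unique(sheet$subject_id))))

  # --- preprocessing ------------------------------------------------------
  pp <- cfg$preprocess
  prot_pp <- preprocess_omics(proteins, max_missing = pp$max_missing,
                              ig_patterns = if (isTRUE(pp$remove_immunoglobulins))
                                ig_default_patterns() else NULL,
                              n_trees = pp$impute_trees,
                              max_iter = pp$impute_max_iter, seed = seed + 11L)
  met_pp <- preprocess_omics(metabolites, max_missing = pp$max_missing,
                             ig_patterns = NULL, n_trees = pp$impute_trees,
                             max_iter = pp$impute_max_iter, seed = seed + 12L)
  for (nm in c("proteins", "metabolites")) {
    lg <- if (nm == "proteins") prot_pp$log else met_pp$log
    log_lines <- c(log_lines, sprintf("%s %s: %d features", nm, lg$stage,
                                      lg$n_features))
  }

  # --- per-contrast analysis ----------------------------------------------
  sel <- cfg$selection; evc <- cfg$evaluation
  analyse <- function(m, ct_name, level, seed_base) {
    ct <- resolve_contrast(ct_name); ct$level <- level
    de <- moderated_t_test(m, sheet, ct,
                           p_threshold = cfg$differential$p_threshold,
                           adjust = cfg$differential$adjust)
    g <- ncol(m$values)
    knn <- serial_knn(m, sheet, ct, k_values = sel$k_values,
                      n_values = seq_len(min(sel$n_max, g)),
                      cv_mode = sel$cv_mode)
    lasso <- lasso_logistic(m, sheet, ct, cv_folds = sel$lasso_folds,
                            rule = sel$lasso_rule, seed = seed_base + 1L)
    forest <- forest_importance(m, sheet, ct, n_trees = sel$forest_trees,
                                top_fraction = sel$top_fraction,
                                seed = seed_base + 2L)
    cons <- consensus(list(knn$signature, lasso, forest))
    candidates <- select_candidates(cons, de, evc$max_candidates)
    gs <- grid_search(m, candidates, sheet, ct,
                      max_subset_size = evc$max_subset_size,
                      linkage = evc$linkage)
    cons_eval <- if (length(cons$features))
      cluster_classify(m, cons$features, sheet, ct, linkage = evc$linkage)
    else NULL
    list(contrast = ct, de = de, knn = knn, lasso = lasso, forest = forest,
         consensus = cons, candidates = candidates, grid = gs,
         consensus_evaluation = cons_eval)
  }

  contrasts <- c("melanoma_vs_control", "metastatic_vs_primary")
  results <- list()
  for (i in seq_along(contrasts)) {
    ct_name <- contrasts[i]
    prot_res <- analyse(prot_pp$matrix, ct_name, evc$protein_level,
                        seed + 100L * i)
    met_res <- analyse(met_pp$matrix, ct_name, evc$metabolite_level,
                       seed + 100L * i + 10L)
    combined <- combine_omics(prot_pp$matrix, met_pp$matrix, sheet)
    ct_comb <- resolve_contrast(ct_name); ct_comb$level <- evc$combined_level
    comb_candidates <- utils::head(
      unique(c(prot_res$grid$signature$features,
               met_res$grid$signature$features,
               prot_res$candidates, met_res$candidates)),
      evc$max_candidates)
    comb_all_eval <- cluster_classify(combined, comb_candidates, sheet,
                                      ct_comb, linkage = evc$linkage)
    comb_gs <- grid_search(combined, comb_candidates, sheet, ct_comb,
                           max_subset_size = evc$max_subset_size,
                           linkage = evc$linkage)
    part <- spearman_similarity_partition(
      combined, comb_candidates,
      k = min(cfg$integration$k_partitions, length(comb_candidates)),
      linkage = evc$linkage)
    results[[ct_name]] <- list(proteins = prot_res, metabolites = met_res,
                               combined = list(matrix = combined,
                                               candidates = comb_candidates,
                                               panel_evaluation = comb_all_eval,
                                               grid = comb_gs,
                                               partition = part))
    log_lines <- c(log_lines,
                   sprintf("%s: consensus %d proteins / %d metabolites; combined grid winner: %s (accuracy %.4f)",
                           ct_name, length(prot_res$consensus$features),
                           length(met_res$consensus$features),
                           paste(comb_gs$signature$features, collapse = "+"),
                           comb_gs$evaluation$accuracy))
  }

  # --- report ---------------------------------------------------------
  de_summary <- function(de) {
    ord <- order(de$p_value)
    list(n_features = nrow(de), n_significant = sum(de$significant),
         top_features = de$feature_id[utils::head(ord, 10)])
  }
  omic_report <- function(res) {
    list(de = de_summary(res$de),
         knn = list(best_k = res$knn$best_k, best_n = res$knn$best_n,
                    best_score = res$knn$best_score, metric = res$knn$metric,
                    features = res$knn$signature$features),
         lasso = list(features = res$lasso$features,
                      lambda = res$lasso$params$lambda),
         forest = list(features = res$forest$features),
         consensus = list(features = res$consensus$features,
                          lenient = res$consensus$lenient),
         candidates = res$candidates,
         grid = list(features = res$grid$signature$features,
                     evaluation = eval_to_list(res$grid$evaluation)),
         consensus_evaluation = if (is.null(res$consensus_evaluation)) NULL
                                else eval_to_list(res$consensus_evaluation))
  }
  report <- list(
    tool = list(name = "evsig",
                version = as.character(utils::packageVersion("evsig"))),
    seed = seed,
    config = cfg[setdiff(names(cfg), "output")],
    preprocessing = list(proteins = prot_pp$log, metabolites = met_pp$log),
    contrasts = lapply(results, function(res) {
      list(proteins = omic_report(res$proteins),
           metabolites = omic_report(res$metabolites),
           combined = list(
             candidates = res$combined$candidates,
             panel_evaluation = eval_to_list(res$combined$panel_evaluation),
             grid = list(features = res$combined$grid$signature$features,
                         evaluation = eval_to_list(res$combined$grid$evaluation)),
             partition = as.list(res$combined$partition$labels)))
    }),
    truth = if (is.null(truth)) NULL else list(
      marker_effects = truth$marker_effects,
      age_marker = truth$age_marker,
      age_marker_rho = truth$age_marker_rho)
  )
  class(report) <- c("ev_run_report", class(report))

  # --- artifacts ---------------------------------------------------------
  outdir <- outdir %||% cfg$output$dir
  if (!is.null(outdir)) {
    dir.create(file.path(outdir, "tables"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(outdir, "signatures"), showWarnings = FALSE)
    jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", dataframe = "rows")
    for (ct_name in names(results)) {
      res <- results[[ct_name]]
      write_de_table(res$proteins$de,
                     file.path(outdir, "tables",
                               sprintf("de_%s_proteins.tsv", ct_name)))
      write_de_table(res$metabolites$de,
                     file.path(outdir, "tables",
                               sprintf("de_%s_metabolites.tsv", ct_name)))
      utils::write.table(res$proteins$knn$grid,
                         file.path(outdir, "tables",
                                   sprintf("knn_grid_%s_proteins.tsv", ct_name)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$combined$grid$leaderboard,
                         file.path(outdir, "tables",
                                   sprintf("leaderboard_%s_combined.tsv", ct_name)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_partition(res$combined$partition,
                      file.path(outdir, "tables",
                                sprintf("partition_%s.tsv", ct_name)),
                      m = res$combined$matrix)
      for (src in c("knn", "lasso", "forest", "consensus")) {
        sig <- if (src == "knn") res$proteins$knn$signature else res$proteins[[src]]
        write_signature(sig, file.path(outdir, "signatures",
                                       sprintf("%s_proteins_%s.json", ct_name, src)))
      }
      write_signature(res$combined$grid$signature,
                      file.path(outdir, "signatures",
                                sprintf("%s_combined_grid.json", ct_name)))
    }
    writeLines(log_lines, file.path(outdir, "log.txt"))
    return(invisible(report))
  }
  attr(report, "log") <- log_lines
  report
}

#' @export
print.ev_run_report <- function(x, ...) {
  cat(sprintf("<ev_run_report> evsig %s, seed %d\n", x$tool$version, x$seed))
  for (ct in names(x$contrasts)) {
    comb <- x$contrasts[[ct]]$combined
    cat(sprintf("  %s: combined grid winner [%s] accuracy %.2f%% (Acc>NIR p = %.3g)\n",
                ct, paste(comb$grid$features, collapse = ", "),
                100 * comb$grid$evaluation$accuracy,
                comb$grid$evaluation$p_acc_gt_nir))
  }
  invisible(x)
}
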