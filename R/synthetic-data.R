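# Seeded generator of study-shaped EV proteomic + metabolomic cohorts with
# known ground truth. The study's raw data are not deposited; these cohorts
# emulate its structure (group sizes, duplicate measurements, feature
# counts and classes, intensity-dependent dropout, designated marker
# effects, age coupling of one marker) so that every downstream stage can
# be exercised against a known truth.

#' Default spiked marker effects
#'
#' Designated marker features and their true log2 effects per contrast.
#' Protein markers carry the gene symbols reported for this biology (PRG4,
#' APOC4, HPR for melanoma vs control; VWF, SERPIND1, TNC, PLG for
#' metastatic vs primary); metabolite markers are phosphatidylcholines and
#' a lysophosphatidylcholine. Effect sizes are generator study conditions,
#' not estimates.
#'
#' @return data.frame with columns `feature`, `contrast`, `log2fc`.
#' @export
default_marker_effects <- function() {
  data.frame(
    feature = c("PRG4", "APOC4", "HPR", "PC ae C34:3", "lysoPC a C18:2",
                "VWF", "SERPIND1", "TNC", "PLG", "PC aa C38:0", "PC ae C44:3"),
    contrast = c(rep("melanoma_vs_control", 5), rep("metastatic_vs_primary", 6)),
    log2fc = c(1.2, 1.0, 0.8, -0.5, -0.4, 0.9, 0.8, 0.5, 0.4, 0.5, -0.3),
    stringsAsFactors = FALSE
  )
}

#' Configure a synthetic EV cohort
#'
#' Defaults reproduce the study's design: 24 primary melanoma, 12
#' metastatic melanoma and 13 healthy-control subjects, two technical
#' replicates each, 257 proteins (including abundant immunoglobulin decoys)
#' and 88 metabolites with the panel's class composition (72
#' glycerophospholipids, 14 sphingolipids, one biogenic amine, one amino
#' acid).
#'
#' @param n_primary,n_metastatic,n_control Subjects per group.
#' @param n_replicates Technical replicates per subject.
#' @param n_proteins,n_metabolites Feature counts.
#' @param n_immunoglobulin_decoys Number of proteins named with
#'   immunoglobulin gene symbols (IGHG1, IGKC, ...) so the removal filter is
#'   testable by name.
#' @param marker_effects data.frame (`feature`, `contrast`, `log2fc`) of
#'   true spiked effects; see [default_marker_effects()].
#' @param mcar_rate Missing-completely-at-random entry rate in `[0, 1]`.
#' @param mnar_slope Logistic steepness of low-intensity dropout (0
#'   disables the intensity-dependent term).
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   log-normal jitter between technical replicates.
#' @param age_marker_rho Target Spearman correlation between `age_marker`
#'   and subject age (realised to within +/- 0.05).
#' @param age_marker Feature coupled to age.
#' @param seed Integer seed governing all randomness.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_primary = 24, n_metastatic = 12, n_control = 13,
                          n_replicates = 2, n_proteins = 257,
                          n_metabolites = 88, n_immunoglobulin_decoys = 15,
                          marker_effects = default_marker_effects(),
                          mcar_rate = 0.02, mnar_slope = 1,
                          replicate_cv = 0.15, age_marker_rho = 0.34,
                          age_marker = "PRG4", seed = 1) {
  cfg <- list(n_primary = n_primary, n_metastatic = n_metastatic,
              n_control = n_control, n_replicates = n_replicates,
              n_proteins = n_proteins, n_metabolites = n_metabolites,
              n_immunoglobulin_decoys = n_immunoglobulin_decoys,
              marker_effects = marker_effects, mcar_rate = mcar_rate,
              mnar_slope = mnar_slope, replicate_cv = replicate_cv,
              age_marker_rho = age_marker_rho, age_marker = age_marker,
              seed = seed)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  counts <- c("n_primary", "n_metastatic", "n_control", "n_replicates",
              "n_proteins", "n_metabolites", "n_immunoglobulin_decoys")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v))
      stop("cohort config field `", f, "` must be a non-negative count", call. = FALSE)
  }
  if (cfg$n_immunoglobulin_decoys > cfg$n_proteins)
    stop("cohort config field `n_immunoglobulin_decoys` exceeds `n_proteins`",
         call. = FALSE)
  for (f in c("mcar_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("cohort config field `", f, "` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(cfg$mnar_slope) || cfg$mnar_slope < 0)
    stop("cohort config field `mnar_slope` must be >= 0", call. = FALSE)
  if (!is.numeric(cfg$replicate_cv) || cfg$replicate_cv < 0)
    stop("cohort config field `replicate_cv` must be >= 0", call. = FALSE)
  if (!is.na(cfg$age_marker_rho) && abs(cfg$age_marker_rho) > 1)
    stop("cohort config field `age_marker_rho` must lie in [-1, 1]", call. = FALSE)
  me <- cfg$marker_effects
  if (!is.null(me) && nrow(me)) {
    if (!all(c("feature", "contrast", "log2fc") %in% names(me)))
      stop("cohort config field `marker_effects` needs columns feature/contrast/log2fc",
           call. = FALSE)
    bad <- setdiff(me$contrast, c("melanoma_vs_control", "metastatic_vs_primary"))
    if (length(bad))
      stop("cohort config field `marker_effects` references unknown contrast(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    known <- c(synthetic_protein_names(cfg$n_proteins, cfg$n_immunoglobulin_decoys),
               synthetic_metabolite_names(cfg$n_metabolites)$name)
    missing_f <- setdiff(me$feature, known)
    if (length(missing_f))
      stop("cohort config field `marker_effects` references feature(s) absent ",
           "from the generated panels: ", paste(missing_f, collapse = ", "),
           call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    stop("cohort config field `seed` must be a single integer", call. = FALSE)
  invisible(cfg)
}

# Marker gene symbols always placed first so designated effects exist.
PROTEIN_MARKERS <- c("PRG4", "APOC4", "HPR", "VWF", "SERPIND1", "TNC", "PLG")
IG_DECOY_NAMES <- c("IGHG1", "IGHG2", "IGHG3", "IGHG4", "IGHM", "IGHA1",
                    "IGHA2", "IGKC", "IGLC1", "IGLC2", "IGLC3", "IGJ",
                    "JCHAIN", "IGLL1", "IGHD", "IGLC6", "IGKV4-1", "IGHV3-23")

synthetic_protein_names <- function(n_proteins, n_ig) {
  if (n_ig > length(IG_DECOY_NAMES))
    ig <- c(IG_DECOY_NAMES, sprintf("IGHV1-%d", seq_len(n_ig - length(IG_DECOY_NAMES))))
  else ig <- IG_DECOY_NAMES[seq_len(n_ig)]
  markers <- PROTEIN_MARKERS[seq_len(min(length(PROTEIN_MARKERS), n_proteins - n_ig))]
  n_fill <- n_proteins - n_ig - length(markers)
  fill <- if (n_fill > 0) sprintf("PROT%03d", seq_len(n_fill)) else character()
  c(markers, ig, fill)[seq_len(n_proteins)]
}

METABOLITE_MARKERS <- c("PC ae C34:3", "lysoPC a C18:2", "PC aa C38:0", "PC ae C44:3")

synthetic_metabolite_names <- function(n_metabolites) {
  n_gly <- round(n_metabolites * 72 / 88)
  n_sph <- round(n_metabolites * 14 / 88)
  n_oth <- n_metabolites - n_gly - n_sph
  carbons <- seq(24, 44, by = 2)
  dbl <- 0:6
  pc_aa <- sprintf("PC aa C%d:%d", rep(carbons, each = length(dbl)), dbl)
  pc_ae <- sprintf("PC ae C%d:%d", rep(carbons, each = length(dbl)), dbl)
  lyso <- sprintf("lysoPC a C%d:%d", rep(seq(14, 28, by = 2), each = 3), 0:2)
  gly_pool <- setdiff(c(pc_aa, pc_ae, lyso), METABOLITE_MARKERS)
  gly <- c(METABOLITE_MARKERS[seq_len(min(4, n_gly))],
           gly_pool[seq_len(max(0, n_gly - 4))])
  sph_pool <- c(sprintf("SM C%d:%d", rep(seq(16, 26, by = 2), each = 2), 0:1),
                sprintf("SM (OH) C%d:%d", rep(seq(14, 24, by = 2), each = 2), 1:2))
  sph <- sph_pool[seq_len(n_sph)]
  oth <- c("Spermidine", "Serine", "Taurine", "Putrescine")[seq_len(max(0, n_oth))]
  data.frame(name = c(gly, sph, oth),
             class = c(rep("glycerophospholipid", length(gly)),
                       rep("sphingolipid", length(sph)),
                       c("biogenic amine", "amino acid", "amino acid",
                         "biogenic amine")[seq_len(max(0, n_oth))]),
             stringsAsFactors = FALSE)[seq_len(n_metabolites), ]
}

#' Generate a synthetic EV cohort
#'
#' Draws subject-level log-normal baselines per feature, applies the
#' configured group effects multiplicatively on designated markers, couples
#' one marker to subject age by rank blending until the realised Spearman
#' correlation is within +/- 0.05 of the target, adds multiplicative
#' log-normal replicate jitter, and injects intensity-dependent (MNAR) plus
#' completely-at-random missingness. Fully reproducible for a fixed seed.
#'
#' @param cfg A [cohort_config()].
#' @return A list with elements `proteins` and `metabolites` (raw-layer
#'   [omics_matrix()] objects), `sheet` (a [sample_sheet()]), and `truth`
#'   (class `synthetic_truth`: spiked effects, per-feature baselines,
#'   missingness parameters, realised age correlation, seed).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_proteins = 40, n_metabolites = 20,
#'                                         n_immunoglobulin_decoys = 4, seed = 3))
#' cohort$proteins
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) cfg <- do.call(cohort_config, cfg)
  validate_cohort_config(cfg)
  set.seed(cfg$seed)

  groups <- c(rep("primary", cfg$n_primary), rep("metastatic", cfg$n_metastatic),
              rep("control", cfg$n_control))
  subj <- c(sprintf("P%02d", seq_len(cfg$n_primary)),
            sprintf("M%02d", seq_len(cfg$n_metastatic)),
            sprintf("C%02d", seq_len(cfg$n_control)))
  ns <- length(subj)
  # Ages match the reported group demographics (older melanoma groups).
  age_mu <- c(primary = 62.67, metastatic = 62.42, control = 34.76)
  age_sd <- c(primary = 15.66, metastatic = 22.48, control = 14.07)
  age <- round(pmin(pmax(stats::rnorm(ns, age_mu[groups], age_sd[groups]), 18), 95))

  subj_sheet <- sample_sheet(subj, subj, groups, 1L, age = age)

  prot_names <- synthetic_protein_names(cfg$n_proteins, cfg$n_immunoglobulin_decoys)
  met <- synthetic_metabolite_names(cfg$n_metabolites)

  draw_subject_matrix <- function(feat, mu, sdg) {
    v <- matrix(stats::rnorm(ns * length(feat), rep(mu, each = ns),
                             rep(sdg, each = ns)),
                ns, length(feat), dimnames = list(subj, feat))
    v
  }

  # Protein baselines: log2 LFQ-like intensities. Markers are fixed at a
  # comfortably quantified level; immunoglobulins are abundant plasma
  # proteins so they survive the missingness filter and exercise removal.
  p_mu <- stats::rnorm(cfg$n_proteins, 25, 3)
  p_sd <- stats::rgamma(cfg$n_proteins, shape = 4, rate = 5)
  names(p_mu) <- names(p_sd) <- prot_names
  p_mu[intersect(PROTEIN_MARKERS, prot_names)] <- 27
  p_sd[intersect(PROTEIN_MARKERS, prot_names)] <- 0.8
  p_mu[grepl("^IG|^JCHAIN", prot_names)] <- 30
  prot_log2 <- draw_subject_matrix(prot_names, p_mu, p_sd)

  # Metabolite baselines: log2 concentrations (uM). Two designated
  # low-abundance features emulate panel members lost to the >40% filter.
  m_mu <- stats::rnorm(cfg$n_metabolites, 0, 2)
  m_sd <- stats::rgamma(cfg$n_metabolites, shape = 4, rate = 5)
  names(m_mu) <- names(m_sd) <- met$name
  m_mu[intersect(METABOLITE_MARKERS, met$name)] <- 1.5
  m_sd[intersect(METABOLITE_MARKERS, met$name)] <- 0.8
  low <- setdiff(met$name, METABOLITE_MARKERS)
  low <- utils::tail(low[met$class[match(low, met$name)] == "glycerophospholipid"], 2)
  m_mu[low] <- -6
  met_log2 <- draw_subject_matrix(met$name, m_mu, m_sd)

  # Spike configured group effects on the subject-level matrices.
  me <- cfg$marker_effects
  truth_effects <- me[0, ]
  spike_log2 <- function(v, effects) {
    for (i in seq_len(nrow(effects))) {
      ct <- resolve_contrast(effects$contrast[i])
      pos <- subj_sheet$subject_id[subj_sheet$group %in% ct$positive]
      v[pos, effects$feature[i]] <- v[pos, effects$feature[i]] + effects$log2fc[i]
    }
    v
  }
  if (!is.null(me) && nrow(me)) {
    me_p <- me[me$feature %in% prot_names, , drop = FALSE]
    me_m <- me[me$feature %in% met$name, , drop = FALSE]
    prot_log2 <- spike_log2(prot_log2, me_p)
    met_log2 <- spike_log2(met_log2, me_m)
    truth_effects <- rbind(me_p, me_m)
  }

  # Couple one marker to age by signed rank blending.
  realised_rho <- NA_real_
  if (!is.na(cfg$age_marker_rho) && cfg$age_marker %in% prot_names) {
    blended <- blend_to_rho(prot_log2[, cfg$age_marker], age,
                            cfg$age_marker_rho, tol = 0.05)
    prot_log2[, cfg$age_marker] <- blended$x
    realised_rho <- blended$rho
  }

  # Replicate expansion with multiplicative log-normal jitter.
  obs <- as.vector(vapply(seq_len(cfg$n_replicates),
                          function(r) paste0(subj, "_r", r), character(ns)))
  rep_of <- rep(subj, times = cfg$n_replicates)
  rep_idx <- rep(seq_len(cfg$n_replicates), each = ns)
  sd_rep <- sqrt(log(1 + cfg$replicate_cv^2)) / log(2)  # cv -> log2 sd
  expand <- function(v) {
    out <- v[rep_of, , drop = FALSE]
    out <- out + matrix(stats::rnorm(length(out), 0, sd_rep), nrow(out), ncol(out))
    rownames(out) <- obs
    out
  }
  prot_raw <- 2^expand(prot_log2)
  met_raw <- 2^expand(met_log2)

  sheet <- sample_sheet(obs, rep_of,
                        subj_sheet$group[match(rep_of, subj_sheet$subject_id)],
                        rep_idx,
                        age = subj_sheet$age[match(rep_of, subj_sheet$subject_id)])

  proteins <- omics_matrix(prot_raw, feature_kind = "protein")
  metabolites <- omics_matrix(met_raw, feature_kind = "metabolite",
                              feature_class = met$class)

  # Intensity-dependent dropout: proteins lose roughly half their features
  # to the >40% rule (midpoint at the median log2 intensity); metabolites
  # are near-complete apart from the designated low-abundance features.
  proteins <- inject_missing(proteins, cfg$mcar_rate, cfg$mnar_slope,
                             seed = cfg$seed + 1L,
                             midpoint = stats::quantile(log2(prot_raw), 0.5))
  metabolites <- inject_missing(metabolites, cfg$mcar_rate, cfg$mnar_slope,
                                seed = cfg$seed + 2L,
                                midpoint = stats::quantile(log2(met_raw), 0.02))

  truth <- structure(list(
    marker_effects = truth_effects,
    baselines = data.frame(
      feature = c(prot_names, met$name),
      kind = c(rep("protein", cfg$n_proteins), rep("metabolite", cfg$n_metabolites)),
      mu_log2 = c(unname(p_mu), unname(m_mu)),
      sd_log2 = c(unname(p_sd), unname(m_sd)),
      stringsAsFactors = FALSE),
    missingness = list(mcar_rate = cfg$mcar_rate, mnar_slope = cfg$mnar_slope),
    age_marker = cfg$age_marker, age_marker_rho = realised_rho,
    seed = cfg$seed), class = "synthetic_truth")

  list(proteins = proteins, metabolites = metabolites, sheet = sheet,
       truth = truth)
}

# internal: blend x toward (signed) age ranks until the realised Spearman
# correlation is within tol of target. Preserves mean and sd of x.
blend_to_rho <- function(x, age, target, tol = 0.05) {
  mu <- mean(x); sdev <- stats::sd(x)
  zx <- as.numeric(scale(x))
  za <- as.numeric(scale(rank(age)))
  mix <- function(w) (1 - abs(w)) * zx + w * za
  f <- function(w) suppressWarnings(stats::cor(mix(w), age, method = "spearman")) - target
  if (abs(f(0)) <= tol) return(list(x = x, rho = f(0) + target))
  r <- tryCatch(stats::uniroot(f, c(-0.999, 0.999), tol = 1e-4),
                error = function(e) NULL)
  w <- if (is.null(r)) if (f(0) < 0) 0.999 else -0.999 else r$root
  out <- mix(w)
  out <- (out - mean(out)) / stats::sd(out) * sdev + mu
  rho <- suppressWarnings(stats::cor(out, age, method = "spearman"))
  list(x = out, rho = rho)
}

resolve_contrast <- function(name) {
  switch(name,
         melanoma_vs_control = melanoma_vs_control(),
         metastatic_vs_primary = metastatic_vs_primary(),
         stop("unknown contrast name: ", name, call. = FALSE))
}

#' Inject missingness into a raw-layer matrix
#'
#' Each entry is masked independently with probability
#' `mcar_rate + (1 - mcar_rate) * plogis(mnar_slope * (midpoint - log2(x)))`;
#' the logistic term models low-intensity dropout (missing not at random)
#' and is disabled entirely when `mnar_slope = 0`. Observed entries are
#' unchanged.
#'
#' @param m Raw-layer [omics_matrix()].
#' @param mcar_rate Completely-at-random masking probability in `[0, 1]`.
#' @param mnar_slope Logistic steepness (>= 0) of the intensity-dependent
#'   term.
#' @param seed Integer seed.
#' @param midpoint Log2 intensity at which the MNAR term equals 0.5;
#'   defaults to the 10% quantile of the observed log2 intensities.
#' @return The matrix with additional entries set to `NA`.
#' @export
inject_missing <- function(m, mcar_rate, mnar_slope, seed,
                           midpoint = NULL) {
  if (m$layer != "raw")
    stop("inject_missing() expects a raw-layer matrix", call. = FALSE)
  if (!is.numeric(mcar_rate) || mcar_rate < 0 || mcar_rate > 1)
    stop("`mcar_rate` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(mnar_slope) || mnar_slope < 0)
    stop("`mnar_slope` must be >= 0", call. = FALSE)
  if (mcar_rate == 0 && mnar_slope == 0) return(m)
  v <- m$values
  if (is.null(midpoint))
    midpoint <- stats::quantile(log2(v[v > 0]), 0.1, na.rm = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  l2 <- suppressWarnings(log2(v))
  p <- mcar_rate
  if (mnar_slope > 0)
    p <- p + (1 - mcar_rate) * stats::plogis(mnar_slope * (midpoint - l2))
  mask <- matrix(stats::runif(length(v)) < p, nrow(v), ncol(v))
  v[mask] <- NA_real_
  m$values <- v
  m
}

#' Spike multiplicative group effects into a matrix
#'
#' Entries of each named feature in the positive group of the named
#' contrast are multiplied by `2^log2fc`. Used by the generator and
#' available directly for constructing test cases.
#'
#' @param m Raw-layer [omics_matrix()].
#' @param sheet [sample_sheet()] covering the matrix observations.
#' @param effects data.frame with columns `feature`, `contrast`, `log2fc`.
#' @return The modified matrix, with the applied effects recorded in
#'   `attr(, "spiked_effects")`.
#' @export
spike_effects <- function(m, sheet, effects) {
  validate_sample_sheet(sheet)
  stopifnot(all(c("feature", "contrast", "log2fc") %in% names(effects)))
  missing_f <- setdiff(effects$feature, feature_ids(m))
  if (length(missing_f))
    stop("spike_effects(): unknown feature(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  sheet <- active_sheet(sheet, m)
  for (i in seq_len(nrow(effects))) {
    ct <- resolve_contrast(effects$contrast[i])
    pos_obs <- sheet$observation_id[sheet$group %in% ct$positive]
    if (!length(pos_obs))
      stop("spike_effects(): no observations in the positive group of ",
           effects$contrast[i], call. = FALSE)
    m$values[pos_obs, effects$feature[i]] <-
      m$values[pos_obs, effects$feature[i]] * 2^effects$log2fc[i]
  }
  attr(m, "spiked_effects") <- effects
  m
}
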