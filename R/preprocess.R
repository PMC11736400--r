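# Preprocessing chain: missingness filter, immunoglobulin removal,
# iterative random-forest imputation, log2 + median-centring normalisation,
# technical-replicate averaging. Stage order is fixed:
# identification filter (at read) -> missingness filter -> immunoglobulin
# removal -> imputation -> normalise/log.

#' Remove features with too many missing values
#'
#' Features missing strictly more than `max_fraction` of their values are
#' removed; survivors keep their order. The boundary case (exactly
#' `max_fraction` missing) is retained, per the strict inequality.
#'
#' @param m Raw-layer [omics_matrix()].
#' @param max_fraction Missingness threshold (default 0.40).
#' @return The filtered matrix, with removed ids in `attr(, "removed_features")`.
#' @export
filter_missing <- function(m, max_fraction = 0.40) {
  frac <- colMeans(is.na(m$values))
  drop <- frac > max_fraction
  out <- subset_features(m, feature_ids(m)[!drop])
  attr(out, "removed_features") <- feature_ids(m)[drop]
  out
}

#' Default immunoglobulin gene-symbol prefixes
#' @return Character vector of case-insensitive prefix patterns.
#' @export
ig_default_patterns <- function() c("IGH", "IGK", "IGL", "IGJ", "JCHAIN")

#' Remove immunoglobulin features by gene-name pattern
#'
#' Immunoglobulins are abundant plasma proteins that can mask differences
#' in low-abundance proteins of interest; they are removed by
#' case-insensitive gene-symbol prefix match.
#'
#' @param m Protein [omics_matrix()].
#' @param patterns Character vector of prefixes (matched case-insensitively
#'   at the start of the feature id).
#' @return The filtered matrix, with removed ids in `attr(, "removed_features")`.
#' @export
remove_immunoglobulins <- function(m, patterns = ig_default_patterns()) {
  rx <- paste0("^(", paste(patterns, collapse = "|"), ")")
  hit <- grepl(rx, feature_ids(m), ignore.case = TRUE)
  out <- subset_features(m, feature_ids(m)[!hit])
  attr(out, "removed_features") <- feature_ids(m)[hit]
  out
}

#' Impute missing values with iterative random forests
#'
#' missForest-style scheme: missing entries are initialised with feature
#' means; features are visited in order of increasing missingness, each
#' regressed on all other features with a random-forest regressor and its
#' missing entries re-predicted; iteration stops when the sum of squared
#' changes of the imputed values increases (the previous iteration's values
#' are kept, as in missForest) or `max_iter` is reached. Deterministic for
#' a fixed seed. Imputed entries are forest predictions, i.e. averages of
#' observed values, so they always lie within the observed range of the
#' feature.
#'
#' @param m Raw-layer [omics_matrix()] after filtering; every feature must
#'   have at least one observed value.
#' @param n_trees Trees per forest (default 100).
#' @param max_iter Maximum sweeps over the features (default 10).
#' @param seed Integer seed.
#' @return The completed matrix with layer `"imputed"`.
#' @export
impute_random_forest <- function(m, n_trees = 100, max_iter = 10, seed = 1) {
  v <- m$values
  miss <- is.na(v)
  if (!any(miss)) return(set_layer(m, "imputed"))
  none_obs <- colSums(!miss) == 0
  if (any(none_obs))
    stop("feature(s) with no observed values: ",
         paste(feature_ids(m)[none_obs], collapse = ", "),
         "; run filter_missing() first", call. = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  # initialise with feature means
  mu <- colMeans(v, na.rm = TRUE)
  for (j in which(colSums(miss) > 0)) v[miss[, j], j] <- mu[j]
  targets <- which(colSums(miss) > 0)
  targets <- targets[order(colSums(miss)[targets])]
  fit_seeds <- sample.int(.Machine$integer.max - 1L, max_iter * length(targets))
  colnames(v) <- NULL  # ranger needs syntactic names; use positions
  xnames <- paste0("x", seq_len(ncol(v)))
  prev_delta <- Inf
  prev_v <- v
  s <- 0L
  for (iter in seq_len(max_iter)) {
    before <- v[miss]
    for (j in targets) {
      s <- s + 1L
      obs_r <- !miss[, j]
      xtr <- as.data.frame(v[obs_r, -j, drop = FALSE])
      names(xtr) <- xnames[-j]
      fit <- ranger::ranger(x = xtr, y = v[obs_r, j], num.trees = n_trees,
                            seed = fit_seeds[s], num.threads = 1,
                            respect.unordered.factors = "ignore")
      xte <- as.data.frame(v[!obs_r, -j, drop = FALSE])
      names(xte) <- xnames[-j]
      v[!obs_r, j] <- stats::predict(fit, data = xte)$predictions
    }
    delta <- sum((v[miss] - before)^2) / max(sum(v[miss]^2), .Machine$double.eps)
    if (delta >= prev_delta) {
      v <- prev_v  # criterion increased: keep previous iteration
      break
    }
    prev_delta <- delta
    prev_v <- v
  }
  colnames(v) <- feature_ids(m)
  m$values <- v
  set_layer(m, "imputed")
}

#' Normalise and log-transform
#'
#' log2 transform followed by per-observation median centring: every
#' observation's median becomes 0, removing global per-sample scale
#' differences. Requires a complete, strictly positive imputed-layer
#' matrix.
#'
#' @param m Imputed-layer [omics_matrix()].
#' @return Matrix with layer `"normalised_log"`.
#' @export
normalize_and_log <- function(m) {
  if (m$layer != "imputed")
    stop("normalize_and_log() expects an imputed-layer matrix; run ",
         "impute_random_forest() first", call. = FALSE)
  v <- m$values
  bad <- which(v <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive value at observation '%s', feature '%s'",
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]), call. = FALSE)
  lv <- log2(v)
  lv <- lv - apply(lv, 1, stats::median)
  m$values <- lv
  set_layer(m, "normalised_log")
}

#' Average technical replicates to subject level
#'
#' One observation per subject, the arithmetic per-feature mean of its
#' non-excluded replicates; the sheet collapses to subject level (the
#' subject id becomes the observation id).
#'
#' @param m An [omics_matrix()] at replicate level.
#' @param sheet Matching [sample_sheet()].
#' @return A list with elements `matrix` and `sheet` at subject level.
#' @export
average_replicates <- function(m, sheet) {
  validate_sample_sheet(sheet)
  sheet <- active_sheet(sheet, m)
  if (!nrow(sheet))
    stop("no non-excluded observations matching the matrix", call. = FALSE)
  m <- subset_observations(m, sheet$observation_id)
  subj <- unique(sheet$subject_id)
  g <- rowsum(m$values, group = sheet$subject_id, reorder = FALSE)
  n <- as.vector(table(factor(sheet$subject_id, levels = rownames(g))))
  g <- g / n
  m$values <- g[subj, , drop = FALSE]
  first <- match(subj, sheet$subject_id)
  out_sheet <- sample_sheet(subj, subj, sheet$group[first], 1L,
                            age = sheet$age[first])
  list(matrix = m, sheet = out_sheet)
}

#' Run the full preprocessing chain
#'
#' Missingness filter, optional immunoglobulin removal (proteins), iterative
#' random-forest imputation, then log2 + median-centring normalisation, with
#' a per-stage feature-count log.
#'
#' @param m Raw-layer [omics_matrix()].
#' @param max_missing Missingness threshold for [filter_missing()].
#' @param ig_patterns Immunoglobulin prefixes, or `NULL` to skip removal
#'   (the default for metabolite matrices).
#' @param n_trees,max_iter,seed Imputation parameters, see
#'   [impute_random_forest()].
#' @return A list: `matrix` (normalised_log layer) and `log` (data.frame of
#'   per-stage feature counts).
#' @export
preprocess_omics <- function(m, max_missing = 0.40,
                             ig_patterns = if (all(m$feature_kind == "protein"))
                               ig_default_patterns() else NULL,
                             n_trees = 100, max_iter = 10, seed = 1) {
  log <- data.frame(stage = "input", n_features = ncol(m$values),
                    stringsAsFactors = FALSE)
  m <- filter_missing(m, max_missing)
  log <- rbind(log, data.frame(stage = "missingness_filter",
                               n_features = ncol(m$values)))
  if (!is.null(ig_patterns)) {
    m <- remove_immunoglobulins(m, ig_patterns)
    log <- rbind(log, data.frame(stage = "immunoglobulin_removal",
                                 n_features = ncol(m$values)))
  }
  m <- impute_random_forest(m, n_trees = n_trees, max_iter = max_iter,
                            seed = seed)
  m <- normalize_and_log(m)
  log <- rbind(log, data.frame(stage = "normalised_log",
                               n_features = ncol(m$values)))
  list(matrix = m, log = log)
}
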