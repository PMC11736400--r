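# Differential abundance and classical statistics: empirical-Bayes
# moderated t per feature, Mann-Whitney, Spearman, ROC-AUC, ANOVA from
# summary statistics, Pearson chi-squared.

# internal: solve trigamma(x) = y by Newton iteration (monotone decreasing,
# convex in 1/x; capped at 50 iterations, tolerance 1e-8).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(50)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

# internal: empirical-Bayes hyperparameters (prior df d0, prior variance
# s0^2) from per-feature sample variances s2 on df residual degrees of
# freedom, by moment matching on e_g = log s_g^2 - psi(d_g/2) + log(d_g/2).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(log(s2)) & df > 0
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  G <- sum(ok)
  if (G < 2) {
    # too few informative variances to estimate spread: flat prior
    return(list(d0 = Inf,
                s0sq = if (G == 1) exp(e + digamma(df[ok] / 2) - log(df[ok] / 2))
                       else mean(s2, na.rm = TRUE)))
  }
  ebar <- mean(e)
  rhs <- mean((e - ebar)^2 * G / (G - 1) - trigamma(df[ok] / 2))
  if (rhs <= 0) {
    d0 <- Inf
    s0sq <- exp(ebar)
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s0sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Empirical-Bayes moderated t-test per feature
#'
#' Two-sample differential abundance with variance moderation: each
#' feature's pooled sample variance is shrunk toward a prior variance
#' estimated across all features by moment matching on the log variances,
#' and the resulting moderated t-statistic gains the prior degrees of
#' freedom. With `prior_df = 0` the statistic reduces to the ordinary
#' pooled-variance two-sample t; with `prior_df = Inf` every feature uses
#' the common prior variance.
#'
#' @param m [omics_matrix()] in the `normalised_log` layer.
#' @param sheet [sample_sheet()].
#' @param ct An [contrast()]; subject-level contrasts average technical
#'   replicates first.
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom (`NULL` = estimate empirically).
#' @param p_threshold Significance threshold (default 0.05, unadjusted, per
#'   the analysis convention; see `adjust`).
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()];
#'   `"none"` (default) leaves p-values unadjusted.
#' @return data.frame with one row per feature: `feature_id`, `log2_fc`
#'   (positive minus negative group mean), `t_mod`, `df`, `p_value`,
#'   `direction`, `significant`; hyperparameters in
#'   `attr(, "prior")`.
#' @export
moderated_t_test <- function(m, sheet, ct, prior_df = NULL,
                             p_threshold = 0.05, adjust = "none") {
  if (m$layer != "normalised_log")
    stop("moderated_t_test() expects the normalised_log layer", call. = FALSE)
  fr <- contrast_frame(m, sheet, ct)
  pos <- fr$values[fr$labels == "positive", , drop = FALSE]
  neg <- fr$values[fr$labels == "negative", , drop = FALSE]
  n1 <- nrow(pos); n2 <- nrow(neg)
  if (n1 < 2) stop("group '", paste(ct$positive, collapse = "+"),
                   "' has fewer than 2 observations", call. = FALSE)
  if (n2 < 2) stop("group '", paste(ct$negative, collapse = "+"),
                   "' has fewer than 2 observations", call. = FALSE)
  m1 <- colMeans(pos); m2 <- colMeans(neg)
  ss1 <- colSums((pos - rep(m1, each = n1))^2)
  ss2 <- colSums((neg - rep(m2, each = n2))^2)
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg
  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, rep(dg, length(s2)))
  } else if (prior_df == 0) {
    prior <- list(d0 = 0, s0sq = NA_real_)
  } else if (is.infinite(prior_df)) {
    prior <- list(d0 = Inf, s0sq = fit_variance_prior(s2, rep(dg, length(s2)))$s0sq)
  } else {
    prior <- list(d0 = prior_df,
                  s0sq = fit_variance_prior(s2, rep(dg, length(s2)))$s0sq)
  }
  s2_post <- if (is.infinite(prior$d0)) rep(prior$s0sq, length(s2))
             else if (prior$d0 == 0) s2
             else (prior$d0 * prior$s0sq + dg * s2) / (prior$d0 + dg)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t_mod <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  df_total <- prior$d0 + dg
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[!is.finite(t_mod) & diff != 0] <- 0
  p_use <- stats::p.adjust(p, method = adjust)
  out <- data.frame(feature_id = feature_ids(m),
                    log2_fc = unname(diff),
                    t_mod = unname(t_mod),
                    df = df_total,
                    p_value = unname(p_use),
                    direction = ifelse(diff >= 0, "up", "down"),
                    significant = unname(p_use < p_threshold),
                    stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  attr(out, "contrast") <- ct$name
  out
}

#' Mann-Whitney U test
#'
#' `W = #\{(i,j): x_i > y_j\} + 0.5 * #\{ties\}` over all cross pairs. The
#' two-sided p-value is exact when `n1 * n2 <= 400` and there are no ties,
#' otherwise a normal approximation with tie and continuity correction is
#' used.
#'
#' @param x,y Non-empty numeric vectors.
#' @return list with `W` and `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y))
    stop("mann_whitney() requires non-empty inputs", call. = FALSE)
  W <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) * length(y) <= 400 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  list(W = unname(W), p = p)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; two-sided p-value from the t
#' approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("spearman_cor() requires length >= 3", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Area under the ROC curve
#'
#' Probability that a positive scores above a negative, counting ties as
#' one half: `(wins + 0.5 * ties) / (n_pos * n_neg)`, computed via
#' mid-ranks.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical, or coercible, positive-class indicator.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("roc_auc() requires both classes present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-way ANOVA from group summaries
#'
#' F statistic from group sizes, means and standard deviations:
#' between-group mean square over within-group mean square.
#'
#' @param ns Integer group sizes (each >= 2).
#' @param means,sds Group means and standard deviations.
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
anova_from_summary <- function(ns, means, sds) {
  k <- length(ns)
  if (k < 2 || length(means) != k || length(sds) != k)
    stop("anova_from_summary() needs >= 2 groups with matching summaries",
         call. = FALSE)
  if (any(ns < 2)) stop("every group must have n >= 2", call. = FALSE)
  N <- sum(ns)
  gm <- sum(ns * means) / N
  msb <- sum(ns * (means - gm)^2) / (k - 1)
  msw <- sum((ns - 1) * sds^2) / (N - k)
  Fstat <- msb / msw
  list(F = Fstat, df_between = k - 1, df_within = N - k,
       p = stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE))
}

#' Pearson chi-squared test of independence
#'
#' Pearson statistic without continuity correction on a two-dimensional
#' non-negative integer table with positive margins.
#'
#' @param table Count matrix.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("chi_square_test() requires a non-negative integer table", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi_square_test() requires positive margins", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Export a differential table as TSV
#'
#' Columns `feature`, `log2FC`, `t`, `p`, `significant`, plus
#' `neg_log10_p` for volcano plotting.
#'
#' @param de A data.frame from [moderated_t_test()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  out <- data.frame(feature = de$feature_id, log2FC = de$log2_fc,
                    t = de$t_mod, p = de$p_value,
                    significant = de$significant,
                    neg_log10_p = -log10(de$p_value))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
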