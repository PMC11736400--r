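# Signature evaluation: unsupervised hierarchical clustering as a 2-class
# classifier, No-Information Rate, exact binomial accuracy test,
# Clopper-Pearson interval, exhaustive grid search, agreement indices, PCA.

#' No-Information Rate
#'
#' Accuracy of always predicting the majority class: the largest class
#' count divided by the number of observations.
#'
#' @param labels Non-empty vector of class labels.
#' @return Proportion in `[1/n_classes, 1]`.
#' @export
nir <- function(labels) {
  if (!length(labels)) stop("nir() requires non-empty labels", call. = FALSE)
  max(table(labels)) / length(labels)
}

#' Exact binomial accuracy-above-NIR test
#'
#' One-sided upper-tail probability `P(X >= correct)` with
#' `X ~ Binomial(n, nir)`: the probability of doing at least this well by
#' always-majority guessing.
#'
#' @param correct Number of correct predictions (0..n).
#' @param n Number of predictions.
#' @param nir Null proportion in (0, 1), usually from [nir()].
#' @return p-value.
#' @export
binomial_acc_test <- function(correct, n, nir) {
  stopifnot(correct >= 0, correct <= n, nir > 0, nir < 1)
  stats::pbinom(correct - 1, n, nir, lower.tail = FALSE)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Via beta-distribution quantiles; the lower bound is 0 when there are no
#' successes and the upper bound 1 when all trials succeed.
#'
#' @param successes,n Counts with `0 <= successes <= n`.
#' @param level Confidence level (default 0.95).
#' @return list with `lo` and `hi`.
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  stopifnot(successes >= 0, successes <= n, n >= 1)
  a <- 1 - level
  lo <- if (successes == 0) 0 else stats::qbeta(a / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else stats::qbeta(1 - a / 2, successes + 1, n - successes)
  list(lo = lo, hi = hi)
}

#' Evaluate a signature by clustering-as-classifier
#'
#' Agglomerative hierarchical clustering (Euclidean distance, complete
#' linkage by default) on the feature-restricted matrix, cut into two
#' clusters; the clusters are mapped to the two contrast classes by the
#' assignment that maximises accuracy. Reports the confusion counts
#' (positive = disease class), accuracy with exact 95% Clopper-Pearson
#' interval, the No-Information Rate, the exact binomial accuracy-above-NIR
#' p-value, sensitivity and specificity, and the evaluation level.
#'
#' @param m [omics_matrix()] in the normalised_log layer.
#' @param features Feature ids to cluster on.
#' @param sheet [sample_sheet()].
#' @param ct [contrast()]; its `level` decides whether evaluation runs on
#'   technical replicates or on subject-averaged observations.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return Object of class `signature_evaluation`.
#' @export
cluster_classify <- function(m, features, sheet, ct, linkage = "complete") {
  if (m$layer != "normalised_log")
    stop("cluster_classify() expects the normalised_log layer", call. = FALSE)
  fr <- contrast_frame(m, sheet, ct)
  missing_f <- setdiff(features, colnames(fr$values))
  if (length(missing_f))
    stop("features absent from matrix: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  if (min(table(fr$labels)) < 2)
    stop("each class needs >= 2 observations", call. = FALSE)
  x <- fr$values[, features, drop = FALSE]
  cl <- stats::cutree(stats::hclust(stats::dist(x), method = linkage), k = 2)
  truth_pos <- fr$labels == "positive"
  # both cluster -> label assignments; keep the more accurate
  acc1 <- mean((cl == 1) == truth_pos)
  acc2 <- mean((cl == 2) == truth_pos)
  pred_pos <- if (acc1 >= acc2) cl == 1 else cl == 2
  tp <- sum(pred_pos & truth_pos)
  fp <- sum(pred_pos & !truth_pos)
  tn <- sum(!pred_pos & !truth_pos)
  fn <- sum(!pred_pos & truth_pos)
  n <- length(truth_pos)
  correct <- tp + tn
  ci <- clopper_pearson(correct, n)
  nir_v <- nir(fr$labels)
  structure(list(features = features, n = n,
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 accuracy = correct / n,
                 ci_low = ci$lo, ci_high = ci$hi,
                 nir = unname(nir_v),
                 p_acc_gt_nir = binomial_acc_test(correct, n, nir_v),
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 level = ct$level, contrast = ct$name, linkage = linkage),
            class = "signature_evaluation")
}

#' @export
print.signature_evaluation <- function(x, ...) {
  cat(sprintf("<signature_evaluation> %s (%s level, n = %d)\n",
              x$contrast, x$level, x$n))
  cat(sprintf("  accuracy %.2f%% (%.2f - %.2f%%), NIR %.2f%%, Acc>NIR p = %.3g\n",
              100 * x$accuracy, 100 * x$ci_low, 100 * x$ci_high,
              100 * x$nir, x$p_acc_gt_nir))
  cat(sprintf("  sensitivity %.2f%%, specificity %.2f%% | features: %s\n",
              100 * x$sensitivity, 100 * x$specificity,
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Exhaustive grid search over candidate feature subsets
#'
#' Every non-empty subset of the candidates up to `max_subset_size` is
#' evaluated with [cluster_classify()]; the winner maximises accuracy, with
#' ties broken toward smaller subsets and then lexicographic feature order
#' (so the result does not depend on candidate input order). Candidate
#' lists are capped at 12 (exhaustive enumeration); pre-filter larger
#' lists, e.g. by consensus or differential-abundance rank.
#'
#' @param m,sheet,ct,linkage As in [cluster_classify()].
#' @param candidates Character vector of 1-12 candidate feature ids.
#' @param max_subset_size Largest subset size to consider.
#' @return list with `signature` (a [feature_signature()], source
#'   `"grid"`), `evaluation` (the winning [cluster_classify()] result) and
#'   `leaderboard` (data.frame over all evaluated subsets).
#' @export
grid_search <- function(m, candidates, sheet, ct,
                        max_subset_size = length(candidates),
                        linkage = "complete") {
  candidates <- unique(candidates)
  if (length(candidates) < 1)
    stop("grid_search() needs at least one candidate", call. = FALSE)
  if (length(candidates) > 12)
    stop("grid_search() enumerates exhaustively and accepts at most 12 ",
         "candidates; pre-filter the list (e.g. by consensus or ",
         "differential-abundance rank)", call. = FALSE)
  candidates <- sort(candidates)
  max_subset_size <- min(max_subset_size, length(candidates))
  evals <- list()
  rows <- list()
  i <- 0L
  for (size in seq_len(max_subset_size)) {
    sets <- utils::combn(candidates, size, simplify = FALSE)
    for (s in sets) {
      i <- i + 1L
      ev <- cluster_classify(m, s, sheet, ct, linkage = linkage)
      evals[[i]] <- ev
      rows[[i]] <- data.frame(features = paste(s, collapse = "+"),
                              size = size, accuracy = ev$accuracy,
                              p_acc_gt_nir = ev$p_acc_gt_nir,
                              sensitivity = ev$sensitivity,
                              specificity = ev$specificity,
                              stringsAsFactors = FALSE)
    }
  }
  lb <- do.call(rbind, rows)
  best_i <- order(-lb$accuracy, lb$size, lb$features)[1]
  best <- evals[[best_i]]
  list(signature = feature_signature(best$features, "grid",
                                     params = list(max_subset_size = max_subset_size,
                                                   n_subsets = nrow(lb))),
       evaluation = best,
       leaderboard = lb[order(-lb$accuracy, lb$size, lb$features), ])
}

#' Agreement between two partitions
#'
#' Adjusted Rand index (Hubert & Arabie) and normalised mutual information
#' (normalised by the mean entropy, `2 I / (H_a + H_b)`), both computed
#' from the contingency table of the two memberships. Identical partitions
#' score 1 on both indices; the ARI of a random partition is 0 in
#' expectation. Two identical one-cluster partitions have NMI 1 by
#' convention.
#'
#' @param partition_a,partition_b Cluster membership vectors over the same
#'   elements.
#' @return list with `ari` and `nmi`.
#' @export
clustering_agreement <- function(partition_a, partition_b) {
  if (length(partition_a) != length(partition_b))
    stop("partitions must cover the same elements", call. = FALSE)
  n <- length(partition_a)
  tab <- table(partition_a, partition_b)
  # adjusted Rand from pair counts
  comb2 <- function(v) sum(v * (v - 1) / 2)
  idx <- comb2(as.vector(tab))
  exp_idx <- comb2(rowSums(tab)) * comb2(colSums(tab)) / comb2(n)
  max_idx <- (comb2(rowSums(tab)) + comb2(colSums(tab))) / 2
  ari <- if (max_idx == exp_idx) 1 else (idx - exp_idx) / (max_idx - exp_idx)
  # mutual information and entropies (natural log)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  nmi <- if (ha + hb == 0) 1 else 2 * mi / (ha + hb)
  list(ari = ari, nmi = nmi)
}

#' Principal-component scores
#'
#' Column-centred singular-value decomposition; scores are returned for the
#' leading components, ordered by decreasing variance.
#'
#' @param m [omics_matrix()].
#' @param n_components Number of components, at most `min(dim(values))`.
#' @return Numeric score matrix (observations x components).
#' @export
pca_scores <- function(m, n_components) {
  v <- m$values
  if (n_components > min(dim(v)))
    stop("`n_components` exceeds min(dim)", call. = FALSE)
  centred <- sweep(v, 2, colMeans(v))
  sv <- svd(centred, nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(rownames(v), paste0("PC", seq_len(n_components)))
  scores
}

#' Export a heatmap-ready ordered matrix
#'
#' Writes the feature-restricted matrix as TSV with rows and columns in
#' dendrogram order (Euclidean distance, the given linkage).
#'
#' @param m [omics_matrix()].
#' @param features Feature ids to include.
#' @param path Output path.
#' @param linkage Agglomeration method.
#' @return `path`, invisibly.
#' @export
write_heatmap_matrix <- function(m, features, path, linkage = "complete") {
  x <- m$values[, features, drop = FALSE]
  ro <- stats::hclust(stats::dist(x), method = linkage)$order
  co <- if (length(features) > 1)
    stats::hclust(stats::dist(t(x)), method = linkage)$order
  else 1L
  out <- data.frame(observation = rownames(x)[ro],
                    x[ro, co, drop = FALSE], check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
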