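# Shared fixtures: small matrices, sheets, and independent oracles used to
# cross-check the package's implementations.

# normalised-log matrix from a plain numeric matrix
nl_matrix <- function(x, kind = "protein") {
  if (is.null(rownames(x))) rownames(x) <- paste0("o", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  omics_matrix(x, feature_kind = kind, layer = "normalised_log")
}

# one-replicate sheet: n_pos primary subjects then n_neg controls
two_group_sheet <- function(n_pos, n_neg, obs = NULL) {
  ids <- obs %||% c(paste0("p", seq_len(n_pos)), paste0("c", seq_len(n_neg)))
  evsig::sample_sheet(ids, ids, rep(c("primary", "control"), c(n_pos, n_neg)), 1L)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# independent k-nearest-neighbour oracle: naive loops, distance ties broken
# toward the lowest training index, majority vote
oracle_knn <- function(train, test, labels, k) {
  out <- character(nrow(test))
  for (i in seq_len(nrow(test))) {
    d <- sqrt(rowSums((train - matrix(test[i, ], nrow(train), ncol(train),
                                      byrow = TRUE))^2))
    nb <- sort.list(d, method = "shell")[seq_len(k)]  # stable on ties
    votes <- table(labels[nb])
    out[i] <- names(votes)[which.max(votes)]
  }
  out
}

# independent clustering-as-classifier oracle: evaluates both cluster ->
# label maps explicitly
oracle_cluster_confusion <- function(x, truth_pos, linkage = "complete") {
  cl <- stats::cutree(stats::hclust(stats::dist(x), method = linkage), k = 2)
  best <- NULL
  for (pos_cluster in 1:2) {
    pred <- cl == pos_cluster
    acc <- mean(pred == truth_pos)
    if (is.null(best) || acc > best$acc)
      best <- list(acc = acc,
                   tp = sum(pred & truth_pos), fp = sum(pred & !truth_pos),
                   tn = sum(!pred & !truth_pos), fn = sum(!pred & truth_pos))
  }
  best
}

# small cohort config for pipeline mechanics tests
small_config <- function(seed = 1) {
  cfg <- default_config(seed = seed)
  cfg$data$n_proteins <- 60
  cfg$data$n_metabolites <- 30
  cfg$data$n_immunoglobulin_decoys <- 5
  cfg$preprocess$impute_trees <- 15
  cfg$selection$forest_trees <- 200
  cfg
}
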