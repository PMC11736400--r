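# A small labelled dataset with two informative and eight noise features,
# one observation per subject (so leave-one-subject-out = leave-one-out).
make_selection_data <- function(seed = 31, n_per_group = 20, informative = 2,
                                noise = 8, shift = 2.5) {
  set.seed(seed)
  n <- 2 * n_per_group
  x <- matrix(rnorm(n * (informative + noise)), n, informative + noise)
  x[seq_len(n_per_group), seq_len(informative)] <-
    x[seq_len(n_per_group), seq_len(informative)] + shift
  colnames(x) <- c(paste0("info", seq_len(informative)),
                   paste0("noise", seq_len(noise)))
  rownames(x) <- paste0("s", seq_len(n))
  m <- nl_matrix(x)
  sheet <- two_group_sheet(n_per_group, n_per_group, obs = rownames(x))
  list(m = m, sheet = sheet, x = x,
       labels = rep(c("positive", "negative"), each = n_per_group))
}

test_that("a perfectly separating top-ranked feature wins at k = 1, N = 1", {
  set.seed(32)
  x <- cbind(sep = rep(c(5, -5), each = 10) + rnorm(20, 0, 0.1),
             noise = rnorm(20))
  rownames(x) <- paste0("s", 1:20)
  m <- nl_matrix(x)
  sheet <- two_group_sheet(10, 10, obs = rownames(x))
  r <- serial_knn(m, sheet, melanoma_vs_control("subject"),
                  k_values = 1, n_values = 1:2)
  expect_identical(r$best_n, 1L)
  expect_identical(r$best_score, 1)
  expect_identical(r$signature$features, "sep")
})

test_that("the serial kNN grid matches an independent brute-force oracle", {
  d <- make_selection_data()
  ct <- melanoma_vs_control("subject")
  de <- moderated_t_test(d$m, d$sheet, ct)
  ranked <- de$feature_id[order(de$p_value)]
  r <- serial_knn(d$m, d$sheet, ct, k_values = c(1, 3, 5), n_values = 1:6,
                  cv_mode = "loso")
  n <- nrow(d$x)
  for (row in seq_len(nrow(r$grid))) {
    k <- r$grid$k[row]; N <- r$grid$N[row]
    pred <- character(n)
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      pred[i] <- oracle_knn(d$x[tr, ranked[seq_len(N)], drop = FALSE],
                            d$x[i, ranked[seq_len(N)], drop = FALSE],
                            d$labels[tr], k)
    }
    expect_equal(r$grid$score[row], mean(pred == d$labels),
                 info = sprintf("k=%d N=%d", k, N))
  }
  # argmax consistent with the grid plus the tie rule
  ord <- order(-r$grid$score, r$grid$N, r$grid$k)
  expect_identical(c(r$best_k, r$best_n),
                   c(r$grid$k[ord[1]], r$grid$N[ord[1]]))
})

test_that("with k = 1 votes, AUC equals balanced accuracy", {
  d <- make_selection_data(seed = 33)
  ct <- melanoma_vs_control("subject")
  acc <- serial_knn(d$m, d$sheet, ct, k_values = 1, n_values = 2,
                    metric = "accuracy")
  auc <- serial_knn(d$m, d$sheet, ct, k_values = 1, n_values = 2,
                    metric = "auc")
  # recompute sens/spec from the oracle votes
  ranked <- acc$ranked_features[1:2]
  n <- nrow(d$x)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    pred[i] <- oracle_knn(d$x[tr, ranked, drop = FALSE],
                          d$x[i, ranked, drop = FALSE], d$labels[tr], 1)
  }
  sens <- mean(pred[d$labels == "positive"] == "positive")
  spec <- mean(pred[d$labels == "negative"] == "negative")
  expect_equal(auc$best_score, (sens + spec) / 2, tolerance = 1e-12)
})

test_that("serial kNN rejects even k and skips oversized N", {
  d <- make_selection_data(seed = 34)
  ct <- melanoma_vs_control("subject")
  expect_error(serial_knn(d$m, d$sheet, ct, k_values = c(1, 2)), "odd")
  expect_message(r <- serial_knn(d$m, d$sheet, ct, k_values = 1,
                                 n_values = c(2, 50)), "skipping")
  expect_equal(unique(r$grid$N), 2)
})

test_that("LASSO selection finds the strong feature and is scale-invariant", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 40
    x <- matrix(rnorm(n * 21), n, 21)
    x[, 1] <- x[, 1] + rep(c(2, 0), each = n / 2)
    colnames(x) <- c("strong", paste0("n", 1:20))
    rownames(x) <- paste0("s", 1:n)
    m <- nl_matrix(x)
    sheet <- two_group_sheet(n / 2, n / 2, obs = rownames(x))
    sig <- lasso_logistic(m, sheet, melanoma_vs_control("subject"), seed = seed)
    if ("strong" %in% sig$features) hits <- hits + 1
    if (seed == 1) {
      # rescaling an input feature leaves the selected set unchanged
      x10 <- x; x10[, 2] <- x10[, 2] * 10
      sig10 <- lasso_logistic(nl_matrix(x10), sheet,
                              melanoma_vs_control("subject"), seed = seed)
      expect_setequal(sig$features, sig10$features)
      # lambda above the null-gradient bound shrinks everything away
      empty <- lasso_logistic(m, sheet, melanoma_vs_control("subject"),
                              seed = seed, lambda = 10)
      expect_length(empty$features, 0)
    }
  }
  expect_gte(hits, 19)
})

test_that("forest importance keeps ceiling(fraction * G) features, strongest first", {
  d <- make_selection_data(seed = 35, noise = 8)
  ct <- melanoma_vs_control("subject")
  sig <- forest_importance(d$m, d$sheet, ct, n_trees = 300, top_fraction = 0.1,
                           seed = 2)
  expect_length(sig$features, 1L)  # ceiling(0.1 * 10)
  expect_true(sig$features %in% c("info1", "info2"))

  wide <- nl_matrix(matrix(rnorm(20 * 107), 20, 107))
  sheetw <- two_group_sheet(10, 10, obs = observation_ids(wide))
  sigw <- forest_importance(wide, sheetw, ct, n_trees = 100,
                            top_fraction = 0.1, seed = 3)
  expect_length(sigw$features, 11L)  # ceiling(10.7)

  expect_identical(
    forest_importance(d$m, d$sheet, ct, n_trees = 300, seed = 9)$features,
    forest_importance(d$m, d$sheet, ct, n_trees = 300, seed = 9)$features)
})

test_that("consensus is the mean-rank-ordered intersection with lenient fallback", {
  expect_identical(consensus(list(c("A", "B", "C"), c("B", "C", "D"),
                                  c("B", "C")))$features, c("B", "C"))

  disjoint <- consensus(list(c("A"), c("B"), c("C")))
  expect_length(disjoint$features, 0)
  expect_length(disjoint$lenient, 0)

  mixed <- consensus(list(c("A", "B"), c("B"), c("A", "B")))
  expect_identical(mixed$features, "B")
  expect_setequal(mixed$lenient, c("A", "B"))

  s <- c("X", "Y", "Z")
  expect_identical(consensus(list(s, s, s))$features, s)

  expect_error(consensus(list(c("A"))), "at least 2")
})
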