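test_that("NIR is the majority-class proportion", {
  expect_identical(nir(rep(c("m", "c"), c(5, 5))), 0.5)
  expect_equal(nir(rep(c("melanoma", "control"), c(34, 13))), 34 / 47)
  expect_error(nir(character()), "non-empty")
})

test_that("the exact binomial accuracy test is an upper-tail probability", {
  expect_equal(binomial_acc_test(3, 3, 0.5), 0.125, tolerance = 1e-12)
  # monotone decreasing in `correct`
  p <- vapply(30:47, binomial_acc_test, numeric(1), n = 47, nir = 34 / 47)
  expect_true(all(diff(p) < 0))
  expect_equal(binomial_acc_test(0, 10, 0.3), 1, tolerance = 1e-12)
})

test_that("Clopper-Pearson intervals hit the documented edge cases", {
  expect_identical(clopper_pearson(0, 10)$lo, 0)
  expect_identical(clopper_pearson(10, 10)$hi, 1)
  ci <- clopper_pearson(5, 10)
  expect_equal(ci$lo, 1 - ci$hi, tolerance = 1e-12)  # symmetric about 0.5
  # interval always contains the point estimate; width shrinks with n
  w <- vapply(c(20, 50, 100, 400), function(n) {
    ci <- clopper_pearson(round(0.7 * n), n)
    expect_gte(0.7 + 1e-6, ci$lo); expect_lte(0.7 - 1e-6, ci$hi)
    ci$hi - ci$lo
  }, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("clustering-as-classifier matches a by-hand oracle and is map-invariant", {
  set.seed(41)
  # two well-separated blobs matching the labels
  x <- rbind(matrix(rnorm(14, 5, 0.3), 7), matrix(rnorm(10, -5, 0.3), 5))
  rownames(x) <- paste0("s", 1:12); colnames(x) <- c("fA", "fB")
  m <- nl_matrix(x)
  sheet <- two_group_sheet(7, 5, obs = rownames(x))
  ev <- cluster_classify(m, c("fA", "fB"), sheet, melanoma_vs_control("subject"))
  expect_identical(ev$accuracy, 1)
  expect_identical(ev$sensitivity, 1)
  expect_identical(ev$specificity, 1)
  expect_equal(ev$nir, 7 / 12)
  expect_identical(ev$level, "subject")

  # overlapping 12-observation instance versus the exhaustive oracle
  x2 <- matrix(rnorm(24, rep(c(1, -1), c(14, 10)), 1.5), 12, 2)
  rownames(x2) <- paste0("s", 1:12); colnames(x2) <- c("fA", "fB")
  m2 <- nl_matrix(x2)
  ev2 <- cluster_classify(m2, c("fA", "fB"), sheet, melanoma_vs_control("subject"))
  oracle <- oracle_cluster_confusion(x2, rep(c(TRUE, FALSE), c(7, 5)))
  expect_identical(unname(ev2$confusion),
                   c(oracle$tp, oracle$fp, oracle$tn, oracle$fn))
  expect_equal(ev2$accuracy, oracle$acc)
  expect_equal(ev2$accuracy, (ev2$confusion[["TP"]] + ev2$confusion[["TN"]]) / ev2$n)
  expect_true(ev2$ci_low <= ev2$accuracy && ev2$accuracy <= ev2$ci_high)
})

test_that("evaluation level follows the contrast (replicate vs subject)", {
  cohort <- generate_cohort(cohort_config(seed = 6, n_proteins = 30,
                                          n_metabolites = 10,
                                          n_immunoglobulin_decoys = 2,
                                          mcar_rate = 0, mnar_slope = 0))
  pp <- preprocess_omics(cohort$proteins, seed = 1)
  ev_rep <- cluster_classify(pp$matrix, c("PRG4", "APOC4"), cohort$sheet,
                             melanoma_vs_control("replicate"))
  ev_sub <- cluster_classify(pp$matrix, c("PRG4", "APOC4"), cohort$sheet,
                             melanoma_vs_control("subject"))
  expect_identical(ev_rep$n, 98L)
  expect_identical(ev_sub$n, 49L)
  expect_equal(ev_rep$nir, 72 / 98)
  expect_equal(ev_sub$nir, 36 / 49)
})

test_that("grid search enumerates subsets and matches a brute-force oracle", {
  set.seed(42)
  n <- 14
  x <- cbind(good1 = rep(c(2, -2), c(8, 6)) + rnorm(n, 0, 0.4),
             good2 = rep(c(2, -2), c(8, 6)) + rnorm(n, 0, 0.4),
             junk1 = rnorm(n), junk2 = rnorm(n))
  rownames(x) <- paste0("s", 1:n)
  m <- nl_matrix(x)
  sheet <- two_group_sheet(8, 6, obs = rownames(x))
  ct <- melanoma_vs_control("subject")

  single <- grid_search(m, "junk1", sheet, ct)
  expect_identical(single$signature$features, "junk1")

  gs <- grid_search(m, colnames(x), sheet, ct, max_subset_size = 4)
  expect_identical(nrow(gs$leaderboard), 15L)  # 2^4 - 1

  # independent exhaustive re-evaluation
  best <- NULL
  for (size in 1:4) for (s in combn(sort(colnames(x)), size, simplify = FALSE)) {
    o <- oracle_cluster_confusion(x[, s, drop = FALSE],
                                  rep(c(TRUE, FALSE), c(8, 6)))
    key <- paste(s, collapse = "+")
    if (is.null(best) || o$acc > best$acc ||
        (o$acc == best$acc && (size < best$size ||
                               (size == best$size && key < best$key))))
      best <- list(acc = o$acc, size = size, key = key, features = s)
  }
  expect_identical(gs$signature$features, best$features)
  expect_equal(gs$evaluation$accuracy, best$acc)

  # winner invariant to candidate input order
  gs_rev <- grid_search(m, rev(colnames(x)), sheet, ct, max_subset_size = 4)
  expect_identical(gs_rev$signature$features, gs$signature$features)

  expect_error(grid_search(m, paste0("f", 1:13), sheet, ct), "at most 12")
})

test_that("partition agreement indices match hand calculation", {
  a <- c(1, 1, 1, 2, 2, 2)
  expect_equal(clustering_agreement(a, a), list(ari = 1, nmi = 1))
  expect_equal(clustering_agreement(1:6, rep(1, 6))$ari, 0)

  b <- c(1, 1, 2, 1, 2, 2)
  # hand-computed contingency: pairs index formula
  tab <- table(a, b)
  sum_comb <- function(v) sum(choose(v, 2))
  idx <- sum_comb(as.vector(tab))
  exp_idx <- sum_comb(rowSums(tab)) * sum_comb(colSums(tab)) / choose(6, 2)
  max_idx <- (sum_comb(rowSums(tab)) + sum_comb(colSums(tab))) / 2
  expect_equal(clustering_agreement(a, b)$ari,
               (idx - exp_idx) / (max_idx - exp_idx), tolerance = 1e-12)

  skip_if_not_installed("mclust")
  set.seed(44)
  p1 <- sample(1:3, 40, replace = TRUE)
  p2 <- sample(1:4, 40, replace = TRUE)
  expect_equal(clustering_agreement(p1, p2)$ari,
               mclust::adjustedRandIndex(p1, p2), tolerance = 1e-12)
})

test_that("PCA scores decompose the variance correctly", {
  set.seed(43)
  # data on a line in 2-D
  t <- rnorm(50)
  line <- cbind(t, 2 * t + 1e-6 * rnorm(50))
  rownames(line) <- paste0("o", 1:50); colnames(line) <- c("a", "b")
  sc <- pca_scores(nl_matrix(line), 2)
  v <- apply(sc, 2, var)
  expect_gt(v[1] / sum(v), 0.999)

  x <- matrix(rnorm(80), 16, 5,
              dimnames = list(paste0("o", 1:16), paste0("f", 1:5)))
  sc2 <- pca_scores(nl_matrix(x), 5)
  cv <- cov(sc2)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)       # orthogonal scores
  expect_equal(sum(diag(cv)), sum(apply(x, 2, var)))  # variance conserved
  expect_error(pca_scores(nl_matrix(x), 6), "exceeds")
})
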