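# Feature selection: serial kNN over (k, N) grids, L1-penalised logistic
# regression, random-forest importance, and their consensus.

#' Construct a feature signature
#'
#' @param features Ordered character vector of unique feature ids.
#' @param source One of `"knn"`, `"lasso"`, `"forest"`, `"consensus"`,
#'   `"grid"`.
#' @param params List of algorithm parameters that produced the signature.
#' @return An object of class `feature_signature`.
#' @export
feature_signature <- function(features, source, params = list()) {
  if (anyDuplicated(features))
    stop("signature features must be unique", call. = FALSE)
  structure(list(features = as.character(features), source = source,
                 params = params),
            class = "feature_signature")
}

#' @export
print.feature_signature <- function(x, ...) {
  cat(sprintf("<feature_signature> source '%s', %d feature(s)\n",
              x$source, length(x$features)))
  if (length(x$features))
    cat(" ", paste(utils::head(x$features, 10), collapse = ", "),
        if (length(x$features) > 10) "..." else "", "\n")
  invisible(x)
}

# internal: k-nearest-neighbour prediction with deterministic tie handling.
# Distance ties are broken toward the lowest training-observation index
# (order() is stable); vote ties cannot arise for odd k with two classes.
# Returns the fraction of the k neighbours voting "positive".
knn_vote <- function(d2, train_labels, k) {
  # d2: n_test x n_train squared distances
  apply(d2, 1, function(row) {
    nb <- order(row)[seq_len(k)]
    mean(train_labels[nb] == "positive")
  })
}

#' Serial k-nearest-neighbour feature selection
#'
#' Sweeps a grid of neighbourhood sizes `k` (odd only, so binary votes
#' cannot tie) and feature-prefix sizes `N` over the features ranked by
#' moderated-t p-value (ascending). Each cell scores a k-nearest-neighbour
#' classifier (Euclidean distance on the top-N features) under
#' cross-validation: leave-one-subject-out by default, so technical
#' replicates of one subject never straddle the train/test split, or
#' leave-one-observation-out (`"loo"`), the convention that treats each
#' replicate as an independent quantification. The best cell maximises the
#' chosen metric; ties break toward smaller N, then smaller k.
#'
#' @param m [omics_matrix()] in the normalised_log layer.
#' @param sheet [sample_sheet()].
#' @param ct [contrast()].
#' @param k_values Odd neighbourhood sizes.
#' @param n_values Feature-prefix sizes (cells with N exceeding the feature
#'   count are skipped with a note).
#' @param metric `"accuracy"` or `"auc"` (AUC of the positive-vote
#'   fraction).
#' @param cv_mode `"loso"` (leave-one-subject-out, default) or `"loo"`.
#' @param ranked_features Optional pre-ranked feature list; defaults to
#'   ranking by [moderated_t_test()] p-value ascending.
#' @return Object of class `serial_knn_result`: `grid` (data.frame `k`,
#'   `N`, `score`), `best_k`, `best_n`, `best_score`, `metric`,
#'   `ranked_features`, and `signature` (a [feature_signature()] of the
#'   winning prefix).
#' @export
serial_knn <- function(m, sheet, ct, k_values = c(1, 3, 5, 7, 9),
                       n_values = 1:10, metric = c("accuracy", "auc"),
                       cv_mode = c("loso", "loo"), ranked_features = NULL) {
  metric <- match.arg(metric)
  cv_mode <- match.arg(cv_mode)
  if (any(k_values %% 2 == 0))
    stop("serial_knn() accepts odd k values only", call. = FALSE)
  if (is.null(ranked_features)) {
    de <- moderated_t_test(m, sheet, ct)
    ranked_features <- de$feature_id[order(de$p_value)]
  }
  fr <- contrast_frame(m, sheet, ct)
  n_obs <- nrow(fr$values)
  n_values <- n_values[n_values >= 1]
  skipped <- n_values[n_values > length(ranked_features)]
  if (length(skipped))
    message("serial_knn(): skipping N > feature count: ",
            paste(skipped, collapse = ", "))
  n_values <- n_values[n_values <= length(ranked_features)]
  x <- fr$values[, ranked_features[seq_len(max(n_values))], drop = FALSE]
  labels <- fr$labels

  # cumulative pairwise squared distances over the ranked feature prefix
  n_max <- max(n_values)
  cum <- vector("list", n_max)
  acc <- matrix(0, n_obs, n_obs)
  for (f in seq_len(n_max)) {
    acc <- acc + outer(x[, f], x[, f], "-")^2
    cum[[f]] <- acc
  }

  folds <- if (cv_mode == "loso") {
    subj <- fr$sheet$subject_id[match(rownames(fr$values),
                                      fr$sheet$observation_id)]
    split(seq_len(n_obs), subj)
  } else {
    as.list(seq_len(n_obs))
  }

  grid <- expand.grid(k = as.integer(sort(k_values)),
                      N = as.integer(sort(n_values)))
  votes <- matrix(NA_real_, n_obs, nrow(grid))
  for (fold in folds) {
    tr <- setdiff(seq_len(n_obs), fold)
    for (g in seq_len(nrow(grid))) {
      k <- grid$k[g]
      if (k > length(tr)) next
      d2 <- cum[[grid$N[g]]][fold, tr, drop = FALSE]
      votes[fold, g] <- knn_vote(d2, labels[tr], k)
    }
  }
  truth <- labels == "positive"
  score_cell <- function(v) {
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    if (metric == "accuracy") mean((v[ok] > 0.5) == truth[ok])
    else roc_auc(v[ok], truth[ok])
  }
  grid$score <- apply(votes, 2, score_cell)
  ranked_grid <- grid[order(-grid$score, grid$N, grid$k), ]
  best <- ranked_grid[1, ]
  structure(list(grid = grid, best_k = best$k, best_n = best$N,
                 best_score = best$score, metric = metric,
                 cv_mode = cv_mode,
                 ranked_features = ranked_features,
                 signature = feature_signature(
                   ranked_features[seq_len(best$N)], "knn",
                   params = list(k = best$k, N = best$N, metric = metric,
                                 cv_mode = cv_mode))),
            class = "serial_knn_result")
}

#' @export
print.serial_knn_result <- function(x, ...) {
  cat(sprintf("<serial_knn_result> best %s = %.4f at k = %d, N = %d (%s CV)\n",
              x$metric, x$best_score, x$best_k, x$best_n, x$cv_mode))
  invisible(x)
}

#' LASSO-penalised logistic regression selection
#'
#' L1-penalised logistic regression over a decreasing lambda path
#' (features standardised internally), with lambda chosen by k-fold
#' cross-validated deviance under the `"min"` or `"1se"` rule; the
#' signature is the set of features with non-zero coefficients at the
#' chosen lambda, ordered by decreasing absolute coefficient.
#'
#' @param m,sheet,ct As in [serial_knn()].
#' @param n_lambda Length of the lambda path.
#' @param cv_folds Number of cross-validation folds.
#' @param rule `"min"` (default) or `"1se"`.
#' @param seed Seed for the fold assignment.
#' @param lambda Optional fixed lambda overriding cross-validation.
#' @return A [feature_signature()] with source `"lasso"`.
#' @export
lasso_logistic <- function(m, sheet, ct, n_lambda = 100, cv_folds = 10,
                           rule = c("min", "1se"), seed = 1, lambda = NULL) {
  rule <- match.arg(rule)
  fr <- contrast_frame(m, sheet, ct)
  x <- fr$values
  y <- fr$labels
  if (is.null(lambda)) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    # complete separation truncates the path at max iterations; that is the
    # documented stopping contract, not an error
    cv <- suppressWarnings(
      glmnet::cv.glmnet(x, y, family = "binomial", nlambda = n_lambda,
                        nfolds = cv_folds, standardize = TRUE,
                        type.measure = "deviance"))
    lambda <- if (rule == "min") cv$lambda.min else cv$lambda.1se
    fit <- cv$glmnet.fit
  } else {
    fit <- suppressWarnings(
      glmnet::glmnet(x, y, family = "binomial", standardize = TRUE,
                     nlambda = n_lambda))
  }
  cf <- as.matrix(stats::coef(fit, s = lambda))[-1, 1]
  nz <- cf[cf != 0]
  feature_signature(names(nz)[order(-abs(nz))], "lasso",
                    params = list(rule = rule, lambda = unname(lambda),
                                  cv_folds = cv_folds))
}

#' Random-forest importance selection
#'
#' Fits a random-forest classifier on all features, ranks features by mean
#' impurity-decrease importance, and returns the top
#' `ceiling(top_fraction * G)`. Deterministic for a fixed seed.
#'
#' @param m,sheet,ct As in [serial_knn()].
#' @param n_trees Number of trees (default 500).
#' @param top_fraction Fraction of features to keep, in `(0, 1]`.
#' @param seed Integer seed.
#' @return A [feature_signature()] with source `"forest"`, ordered by
#'   decreasing importance.
#' @export
forest_importance <- function(m, sheet, ct, n_trees = 500,
                              top_fraction = 0.10, seed = 1) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("`top_fraction` must lie in (0, 1]", call. = FALSE)
  fr <- contrast_frame(m, sheet, ct)
  xdf <- as.data.frame(fr$values)
  names(xdf) <- paste0("x", seq_len(ncol(xdf)))
  fit <- ranger::ranger(x = xdf, y = fr$labels, num.trees = n_trees,
                        importance = "impurity",
                        seed = as.integer(seed %% .Machine$integer.max),
                        num.threads = 1)
  imp <- fit$variable.importance
  n_keep <- ceiling(top_fraction * ncol(fr$values))
  top <- order(-imp)[seq_len(n_keep)]
  feature_signature(colnames(fr$values)[top], "forest",
                    params = list(n_trees = n_trees,
                                  top_fraction = top_fraction))
}

#' Consensus of feature signatures
#'
#' Intersection of the input signatures, ordered by mean rank across
#' sources. When the strict intersection is empty a lenient set is also
#' reported: the union of all pairwise intersections.
#'
#' @param signatures List of at least two [feature_signature()] objects (or
#'   plain character vectors).
#' @return A [feature_signature()] with source `"consensus"` and an extra
#'   element `lenient` (character vector, ordered by mean rank across the
#'   sources containing each feature).
#' @export
consensus <- function(signatures) {
  if (length(signatures) < 2)
    stop("consensus() requires at least 2 signatures", call. = FALSE)
  sets <- lapply(signatures, function(s)
    if (inherits(s, "feature_signature")) s$features else as.character(s))
  mean_rank <- function(feats) {
    vapply(feats, function(f) {
      r <- vapply(sets, function(s) {
        i <- match(f, s)
        if (is.na(i)) NA_real_ else as.numeric(i)
      }, numeric(1))
      mean(r, na.rm = TRUE)
    }, numeric(1))
  }
  inter <- Reduce(intersect, sets)
  inter <- inter[order(mean_rank(inter), inter)]
  lenient <- character()
  pair_idx <- utils::combn(length(sets), 2)
  for (j in seq_len(ncol(pair_idx)))
    lenient <- union(lenient, intersect(sets[[pair_idx[1, j]]],
                                        sets[[pair_idx[2, j]]]))
  lenient <- lenient[order(mean_rank(lenient), lenient)]
  out <- feature_signature(inter, "consensus",
                           params = list(n_sources = length(sets)))
  out$lenient <- lenient
  out
}

#' Write a feature signature as JSON
#' @param sig A [feature_signature()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  jsonlite::write_json(list(source = sig$source, params = sig$params,
                            features = sig$features,
                            lenient = sig$lenient),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
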