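# Multi-omic integration: subject-level concatenation and Spearman
# similarity-matrix partitioning.

#' Combine proteomic and metabolomic matrices at subject level
#'
#' Replicate-level matrices are averaged to subject level, then features
#' are concatenated; feature kinds and classes are preserved. The subject
#' sets of the two matrices must coincide.
#'
#' @param proteins,metabolites [omics_matrix()] objects in the
#'   normalised_log layer (replicate- or subject-level).
#' @param sheet [sample_sheet()] covering both.
#' @return A subject-level `omics_matrix` with `p + m` features.
#' @export
combine_omics <- function(proteins, metabolites, sheet) {
  if (proteins$layer != "normalised_log" || metabolites$layer != "normalised_log")
    stop("combine_omics() expects normalised_log matrices", call. = FALSE)
  to_subject <- function(m) {
    ids <- observation_ids(m)
    sh <- active_sheet(sheet)
    if (any(ids %in% sh$observation_id))
      average_replicates(m, sheet)$matrix
    else m  # already subject-level
  }
  p <- to_subject(proteins)
  mm <- to_subject(metabolites)
  only_p <- setdiff(observation_ids(p), observation_ids(mm))
  only_m <- setdiff(observation_ids(mm), observation_ids(p))
  if (length(only_p) || length(only_m))
    stop("subject sets differ between omics; only in proteins: [",
         paste(only_p, collapse = ", "), "]; only in metabolites: [",
         paste(only_m, collapse = ", "), "]", call. = FALSE)
  mm <- subset_observations(mm, observation_ids(p))
  dup <- intersect(feature_ids(p), feature_ids(mm))
  if (length(dup))
    stop("duplicate feature ids across omics: ", paste(dup, collapse = ", "),
         call. = FALSE)
  omics_matrix(cbind(p$values, mm$values),
               feature_kind = c(p$feature_kind, mm$feature_kind),
               feature_class = c(p$feature_class, mm$feature_class),
               layer = "normalised_log")
}

#' Partition features by Spearman similarity
#'
#' Pairwise Spearman correlation of features across observations;
#' hierarchical clustering of features on the distance `1 - rho`
#' (anticorrelated features are far apart), cut into `k` partitions.
#' Constant features (undefined correlation) are assigned `rho = 0` to all
#' others, with a warning.
#'
#' @param m [omics_matrix()].
#' @param features Feature ids to partition (default: all).
#' @param k Number of partitions (`1 <= k <= length(features)`).
#' @param linkage Agglomeration method.
#' @return Object of class `similarity_partition`: `feature_ids`, `labels`
#'   (named integer partition per feature), `k`, `linkage`, `distance`.
#' @export
spearman_similarity_partition <- function(m, features = feature_ids(m), k,
                                          linkage = "complete") {
  if (k < 1 || k > length(features))
    stop("`k` must lie in [1, number of features]", call. = FALSE)
  x <- m$values[, features, drop = FALSE]
  const <- apply(x, 2, function(col) stats::sd(col) == 0)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  if (any(const)) {
    warning("constant feature(s) assigned zero correlation: ",
            paste(features[const], collapse = ", "))
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  diag(rho) <- 1
  labels <- if (length(features) == 1) stats::setNames(1L, features)
  else stats::cutree(stats::hclust(stats::as.dist(1 - rho), method = linkage),
                     k = k)
  structure(list(feature_ids = features, labels = labels, k = k,
                 linkage = linkage, distance = "1 - Spearman rho"),
            class = "similarity_partition")
}

#' Are two features co-partitioned?
#'
#' @param partition A [spearman_similarity_partition()] result.
#' @param a,b Feature ids present in the partition.
#' @return `TRUE` iff both features carry the same partition label.
#' @export
co_partitioned <- function(partition, a, b) {
  for (f in c(a, b))
    if (!f %in% partition$feature_ids)
      stop("feature not in partition: ", f, call. = FALSE)
  unname(partition$labels[a] == partition$labels[b])
}

#' Export a similarity partition as TSV
#' @param partition A `similarity_partition`.
#' @param m The matrix the partition was computed from (for feature kinds);
#'   optional.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path, m = NULL) {
  df <- data.frame(feature = partition$feature_ids,
                   kind = if (is.null(m)) NA_character_
                          else unname(m$feature_kind[partition$feature_ids]),
                   partition = unname(partition$labels[partition$feature_ids]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
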