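# Core containers: omics matrix, sample sheet, contrast.

#' Construct an observations-by-features omics matrix
#'
#' Lightweight container for a quantitative feature table from a single
#' omics layer (label-free proteomics intensities or targeted-metabolomics
#' concentrations in uM). Rows are observations (technical replicates or
#' subjects), columns are features. The `layer` tag records where the
#' matrix sits in the preprocessing chain: `"raw"` values may contain `NA`
#' for unquantified entries and must be non-negative where observed;
#' `"imputed"` values are complete and positive; `"normalised_log"` values
#' are complete log2, per-observation median-centred quantities.
#'
#' @param values Numeric matrix, observations x features, with unique row
#'   (observation id) and column (feature id) names.
#' @param feature_kind Either a single string or a per-feature character
#'   vector; each entry one of `"protein"` or `"metabolite"`.
#' @param feature_class Optional per-feature character vector of metabolite
#'   classes (e.g. `"glycerophospholipid"`, `"sphingolipid"`); `NA` for
#'   features without a class annotation.
#' @param layer One of `"raw"`, `"imputed"`, `"normalised_log"`.
#'
#' @return An object of class `omics_matrix`: a list with elements
#'   `values`, `feature_kind`, `feature_class`, `layer`.
#' @export
#' @examples
#' x <- matrix(2^rnorm(12, 20), 3, 4,
#'             dimnames = list(paste0("S", 1:3, "_r1"), paste0("P", 1:4)))
#' m <- omics_matrix(x)
#' m
omics_matrix <- function(values, feature_kind = "protein", feature_class = NULL,
                         layer = c("raw", "imputed", "normalised_log")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (observations x features)", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry observation row names and feature column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate observation ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  g <- ncol(values)
  if (length(feature_kind) == 1L) feature_kind <- rep(feature_kind, g)
  if (length(feature_kind) != g)
    stop("`feature_kind` must have one entry per feature", call. = FALSE)
  if (!all(feature_kind %in% c("protein", "metabolite")))
    stop("`feature_kind` entries must be 'protein' or 'metabolite'", call. = FALSE)
  if (is.null(feature_class)) feature_class <- rep(NA_character_, g)
  if (length(feature_class) != g)
    stop("`feature_class` must have one entry per feature", call. = FALSE)
  names(feature_kind) <- names(feature_class) <- colnames(values)
  if (layer == "raw" && any(values < 0, na.rm = TRUE))
    stop("raw-layer values must be >= 0 where observed", call. = FALSE)
  if (layer != "raw" && anyNA(values))
    stop("layer '", layer, "' must contain no missing values", call. = FALSE)
  structure(list(values = values,
                 feature_kind = stats::setNames(as.character(feature_kind), colnames(values)),
                 feature_class = stats::setNames(as.character(feature_class), colnames(values)),
                 layer = layer),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %d observations x %d features, layer '%s'\n",
              nrow(x$values), ncol(x$values), x$layer))
  kinds <- table(x$feature_kind)
  cat("  kinds:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  nm <- sum(is.na(x$values))
  if (nm > 0)
    cat(sprintf("  missing entries: %d (%.1f%%)\n", nm, 100 * nm / length(x$values)))
  invisible(x)
}

#' Feature and observation ids of an omics matrix
#' @param m An `omics_matrix`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(m) colnames(m$values)

#' @rdname feature_ids
#' @export
observation_ids <- function(m) rownames(m$values)

#' Subset an omics matrix
#'
#' @param m An `omics_matrix`.
#' @param features,observations Character vectors of ids to keep (order is
#'   respected).
#' @return An `omics_matrix` restricted to the requested ids.
#' @export
subset_features <- function(m, features) {
  missing_f <- setdiff(features, feature_ids(m))
  if (length(missing_f))
    stop("unknown features: ", paste(missing_f, collapse = ", "), call. = FALSE)
  m$values <- m$values[, features, drop = FALSE]
  m$feature_kind <- m$feature_kind[features]
  m$feature_class <- m$feature_class[features]
  m
}

#' @rdname subset_features
#' @export
subset_observations <- function(m, observations) {
  missing_o <- setdiff(observations, observation_ids(m))
  if (length(missing_o))
    stop("unknown observations: ", paste(missing_o, collapse = ", "), call. = FALSE)
  m$values <- m$values[observations, , drop = FALSE]
  m
}

# internal: change layer tag with validation
set_layer <- function(m, layer) {
  omics_matrix(m$values, m$feature_kind, m$feature_class, layer = layer)
}

#' Construct a sample sheet
#'
#' Observation-level metadata linking technical replicates to subjects and
#' study groups. Observations flagged `excluded` (e.g. outlier samples)
#' never enter analysis operations.
#'
#' @param observation_id,subject_id Character vectors.
#' @param group Character vector; each entry one of `"primary"`,
#'   `"metastatic"`, `"control"`.
#' @param replicate_index Integer replicate index within subject.
#' @param age Optional numeric age in years (per observation; constant
#'   within subject).
#' @param excluded Logical flag; excluded observations are dropped from all
#'   analyses.
#' @param exclusion_reason Free-text reason for exclusion.
#' @return A `data.frame` with class `sample_sheet`.
#' @export
sample_sheet <- function(observation_id, subject_id, group, replicate_index,
                         age = NA_real_, excluded = FALSE,
                         exclusion_reason = NA_character_) {
  df <- data.frame(observation_id = as.character(observation_id),
                   subject_id = as.character(subject_id),
                   group = as.character(group),
                   replicate_index = as.integer(replicate_index),
                   age = as.numeric(age),
                   excluded = as.logical(excluded),
                   exclusion_reason = as.character(exclusion_reason),
                   stringsAsFactors = FALSE)
  validate_sample_sheet(df)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

validate_sample_sheet <- function(sheet) {
  req <- c("observation_id", "subject_id", "group", "replicate_index")
  miss <- setdiff(req, names(sheet))
  if (length(miss))
    stop("sample sheet lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sheet$observation_id))
    stop("sample sheet observation_id values must be unique", call. = FALSE)
  bad <- setdiff(unique(sheet$group), c("primary", "metastatic", "control"))
  if (length(bad))
    stop("unknown group(s): ", paste(bad, collapse = ", "),
         " (expected primary/metastatic/control)", call. = FALSE)
  invisible(sheet)
}

# internal: non-excluded rows of the sheet, optionally aligned to a matrix
active_sheet <- function(sheet, m = NULL) {
  if (is.null(sheet$excluded)) sheet$excluded <- FALSE
  sheet <- sheet[!sheet$excluded, , drop = FALSE]
  if (!is.null(m)) {
    keep <- sheet$observation_id %in% observation_ids(m)
    sheet <- sheet[keep, , drop = FALSE]
    sheet <- sheet[match(intersect(observation_ids(m), sheet$observation_id),
                         sheet$observation_id), , drop = FALSE]
  }
  sheet
}

#' Define a two-group contrast
#'
#' @param name Contrast name (used to resolve spiked effects and label
#'   outputs).
#' @param positive,negative Character vectors of study groups forming the
#'   positive (disease) and negative class; must be disjoint and non-empty.
#' @param level `"subject"` or `"replicate"`: the unit at which the
#'   contrast is analysed. Operations given a replicate-level matrix with a
#'   subject-level contrast average technical replicates first.
#' @return An object of class `ev_contrast`.
#' @export
#' @examples
#' contrast("melanoma_vs_control", c("primary", "metastatic"), "control")
contrast <- function(name, positive, negative,
                     level = c("subject", "replicate")) {
  level <- match.arg(level)
  if (!length(positive) || !length(negative))
    stop("contrast groups must be non-empty", call. = FALSE)
  if (length(intersect(positive, negative)))
    stop("contrast groups must be disjoint", call. = FALSE)
  ok <- c("primary", "metastatic", "control")
  bad <- setdiff(c(positive, negative), ok)
  if (length(bad))
    stop("unknown group(s) in contrast: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(name = name, positive = positive, negative = negative,
                 level = level),
            class = "ev_contrast")
}

#' Built-in study contrasts
#'
#' The two comparisons of the study design: all melanoma subjects versus
#' healthy controls, and metastatic versus primary melanoma.
#'
#' @param level `"subject"` or `"replicate"` (see [contrast()]).
#' @return An `ev_contrast`.
#' @export
melanoma_vs_control <- function(level = c("subject", "replicate"))
  contrast("melanoma_vs_control", c("primary", "metastatic"), "control",
           level = match.arg(level))

#' @rdname melanoma_vs_control
#' @export
metastatic_vs_primary <- function(level = c("subject", "replicate"))
  contrast("metastatic_vs_primary", "metastatic", "primary",
           level = match.arg(level))

# internal: align a matrix + sheet to a contrast.
# Averages replicates when the contrast is subject-level and the matrix is
# replicate-level. Returns list(values, labels) where labels is a factor
# with levels c("negative", "positive"), rows restricted to the contrast's
# groups and non-excluded observations.
contrast_frame <- function(m, sheet, ct) {
  sheet <- active_sheet(sheet)
  ids <- observation_ids(m)
  if (!any(sheet$observation_id %in% ids) && any(sheet$subject_id %in% ids)) {
    # matrix already collapsed to subject level; collapse the sheet to match
    first <- !duplicated(sheet$subject_id)
    sheet <- sample_sheet(sheet$subject_id[first], sheet$subject_id[first],
                          sheet$group[first], 1L, age = sheet$age[first])
  } else if (ct$level == "subject" &&
             any(duplicated(sheet$subject_id[sheet$observation_id %in% ids]))) {
    avg <- average_replicates(m, sheet)
    m <- avg$matrix
    sheet <- avg$sheet
  }
  sheet <- active_sheet(sheet, m)
  grp <- sheet$group
  lab <- rep(NA_character_, nrow(sheet))
  lab[grp %in% ct$positive] <- "positive"
  lab[grp %in% ct$negative] <- "negative"
  keep <- !is.na(lab)
  ids <- sheet$observation_id[keep]
  vals <- m$values[ids, , drop = FALSE]
  labels <- factor(lab[keep], levels = c("negative", "positive"))
  if (!all(c("negative", "positive") %in% labels[drop = TRUE]))
    stop("contrast '", ct$name, "': a class is absent from the data", call. = FALSE)
  list(values = vals, labels = labels,
       sheet = sheet[keep, , drop = FALSE], matrix = subset_observations(m, ids))
}
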