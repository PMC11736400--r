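# Readers and writers: MaxQuant proteinGroups dialect, generic feature
# tables, sample sheets.

MAXQUANT_REQUIRED <- c("Protein IDs", "Gene names", "Reverse",
                       "Potential contaminant", "Only identified by site")

#' Read a MaxQuant proteinGroups table
#'
#' Parses the tab-delimited proteinGroups output of MaxQuant into a
#' raw-layer [omics_matrix()]. One feature per protein group, keyed by gene
#' name with the protein id as fallback; `LFQ intensity <observation>`
#' columns become matrix rows; `0` is re-coded as missing per the format's
#' convention. With `filter_ids = TRUE` (the identification filter), rows
#' flagged `Reverse`, `Potential contaminant` or `Only identified by site`
#' are dropped as unreliable identifications.
#'
#' @param path Path to a tab-delimited proteinGroups file.
#' @param filter_ids Drop flagged rows? Default `TRUE`.
#' @return A raw-layer `omics_matrix` of protein features.
#' @export
read_maxquant_protein_groups <- function(path, filter_ids = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(MAXQUANT_REQUIRED, names(df))
  if (length(miss))
    stop("not a proteinGroups table: missing column(s) ",
         paste(sprintf("'%s'", miss), collapse = ", "), call. = FALSE)
  lfq_cols <- grep("^LFQ intensity ", names(df), value = TRUE)
  if (!length(lfq_cols))
    stop("not a proteinGroups table: no 'LFQ intensity <observation>' columns",
         call. = FALSE)
  if (filter_ids) {
    flagged <- df$Reverse == "+" | df$`Potential contaminant` == "+" |
      df$`Only identified by site` == "+"
    df <- df[!flagged, , drop = FALSE]
  }
  ids <- ifelse(is.na(df$`Gene names`) | df$`Gene names` == "",
                df$`Protein IDs`, df$`Gene names`)
  ids <- make.unique(ids)
  vals <- t(as.matrix(df[, lfq_cols, drop = FALSE]))
  if (!is.numeric(vals))
    stop("non-numeric LFQ intensity values in ", path, call. = FALSE)
  vals[vals == 0] <- NA_real_
  rownames(vals) <- sub("^LFQ intensity ", "", lfq_cols)
  colnames(vals) <- ids
  omics_matrix(vals, feature_kind = "protein", layer = "raw")
}

#' Write an omics matrix in MaxQuant proteinGroups dialect
#'
#' Tab-delimited, one row per protein group, with `LFQ intensity <obs>`
#' columns (missing written as 0 per the format) and the identification
#' flag columns. Optionally appends flagged decoy rows (reverse hits,
#' potential contaminants, identified-by-site-only) so the identification
#' filter of [read_maxquant_protein_groups()] can be exercised.
#'
#' @param m Raw-layer protein `omics_matrix`.
#' @param path Output path.
#' @param flagged_decoys Number of flagged rows to append (cycled over the
#'   three flag kinds).
#' @return `path`, invisibly.
#' @export
write_maxquant_protein_groups <- function(m, path, flagged_decoys = 0) {
  v <- m$values
  v[is.na(v)] <- 0
  df <- data.frame(`Protein IDs` = paste0("SYN_", gsub("[^A-Za-z0-9]", "_", colnames(v))),
                   `Gene names` = colnames(v),
                   Reverse = "", `Potential contaminant` = "",
                   `Only identified by site` = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  lfq <- as.data.frame(t(v))
  names(lfq) <- paste("LFQ intensity", rownames(v))
  df <- cbind(df, lfq)
  if (flagged_decoys > 0) {
    kinds <- rep_len(c("Reverse", "Potential contaminant", "Only identified by site"),
                     flagged_decoys)
    dec <- df[rep(1, flagged_decoys), , drop = FALSE]
    dec$`Protein IDs` <- sprintf("REV__DECOY%03d", seq_len(flagged_decoys))
    dec$`Gene names` <- sprintf("DECOY%03d", seq_len(flagged_decoys))
    dec[grep("^LFQ intensity", names(dec))] <- 0
    for (k in unique(kinds)) dec[[k]] <- ifelse(kinds == k, "+", "")
    df <- rbind(df, dec)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a generic feature table
#'
#' CSV (or TSV, by file extension) with features as rows: a `feature_id`
#' column, an optional `feature_class` column, and one numeric column per
#' observation. Empty cells are missing; non-numeric cells are rejected
#' with their coordinates. Round-trips preserve values to at least 12
#' significant digits.
#'
#' @param path File path; `.tsv`/`.txt` is read tab-delimited, anything
#'   else comma-delimited.
#' @param feature_kind Kind assigned to all features on read.
#' @param layer Layer tag assigned on read.
#' @return `read_feature_table()` returns an [omics_matrix()];
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path, feature_kind = "metabolite",
                               layer = "raw") {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!"feature_id" %in% names(df))
    stop("feature table lacks a 'feature_id' column", call. = FALSE)
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(df$feature_id[duplicated(df$feature_id)]), collapse = ", "),
         call. = FALSE)
  cls <- NULL
  if ("feature_class" %in% names(df)) {
    cls <- df$feature_class
    cls[cls == ""] <- NA_character_
  }
  obs_cols <- setdiff(names(df), c("feature_id", "feature_class"))
  if (!length(obs_cols))
    stop("feature table has no observation columns", call. = FALSE)
  num <- matrix(NA_real_, nrow(df), length(obs_cols),
                dimnames = list(df$feature_id, obs_cols))
  for (j in seq_along(obs_cols)) {
    raw <- df[[obs_cols[j]]]
    raw[raw == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(parsed))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at feature row %d, observation column '%s'",
                   raw[bad[1]], bad[1], obs_cols[j]), call. = FALSE)
    num[, j] <- parsed
  }
  omics_matrix(t(num), feature_kind = feature_kind, feature_class = cls,
               layer = layer)
}

#' @rdname read_feature_table
#' @param m An [omics_matrix()] to write.
#' @export
write_feature_table <- function(m, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  v <- t(m$values)
  df <- data.frame(feature_id = rownames(v), stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!all(is.na(m$feature_class))) df$feature_class <- unname(m$feature_class)
  for (j in colnames(v)) df[[j]] <- format(v[, j], digits = 15, trim = TRUE)
  df[] <- lapply(df, function(col) ifelse(col == "NA", "", col))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet CSV
#'
#' Requires header columns `observation_id`, `subject_id`, `group`,
#' `replicate_index`; optional `age`, `excluded`, `exclusion_reason`.
#'
#' @param path CSV path.
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("observation_id", "subject_id", "group", "replicate_index")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("sample sheet lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  sample_sheet(df$observation_id, df$subject_id, df$group, df$replicate_index,
               age = if ("age" %in% names(df)) df$age else NA_real_,
               excluded = if ("excluded" %in% names(df)) df$excluded else FALSE,
               exclusion_reason = if ("exclusion_reason" %in% names(df))
                 df$exclusion_reason else NA_character_)
}

#' Write a sample sheet CSV
#' @param sheet A [sample_sheet()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
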