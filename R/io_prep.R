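# Reading/writing expression matrices and sample tables, cohort merging,
# and linear-model batch-effect removal.
#
# Matrices are plain numeric matrices, features in rows, samples in columns,
# assumed already normalized on the log2 scale. Sample metadata travels as a
# data.frame ("sample table") with columns sample_id, group (control/case),
# batch, excluded, exclusion_reason.

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample ids and a first column of feature ids,
#' values on the log2 scale. Parsing is strict: ragged rows, empty files and
#' non-numeric cells (including `NA`) raise errors naming the offending line
#' and column — none of the downstream stages defines an imputation rule, so
#' missing values are rejected at the door. Duplicate feature ids are
#' collapsed by keeping the row with the highest mean expression (the usual
#' deterministic rule when array probes map to one symbol).
#'
#' @param path path to a TSV file.
#' @return numeric matrix, features x samples.
#' @seealso [write_expression()], [merge_cohorts()]
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_cf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_cf("parse error in %s: empty or header-only file", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  ncol_expected <- length(header)
  if (ncol_expected < 2L) stop_cf("parse error in %s line 1: no sample columns", path)
  sample_ids <- header[-1]
  n <- length(lines) - 1L
  ids <- character(n)
  vals <- matrix(NA_real_, n, ncol_expected - 1L)
  for (i in seq_len(n)) {
    row <- cells[[i + 1L]]
    if (length(row) != ncol_expected)
      stop_cf("parse error in %s line %d: %d fields, expected %d",
              path, i + 1L, length(row), ncol_expected)
    ids[i] <- row[1]
    v <- suppressWarnings(as.numeric(row[-1]))
    bad <- which(is.na(v))
    if (length(bad))
      stop_cf("parse error in %s line %d column %d: non-numeric cell '%s'",
              path, i + 1L, bad[1] + 1L, row[bad[1] + 1L])
    vals[i, ] <- v
  }
  if (anyDuplicated(sample_ids)) stop_cf("parse error in %s: duplicate sample ids", path)
  rownames(vals) <- ids
  colnames(vals) <- sample_ids
  collapse_duplicate_features(vals)
}

# keep, per duplicated feature id, the row with the highest mean
collapse_duplicate_features <- function(x) {
  if (!anyDuplicated(rownames(x))) return(x)
  m <- rowMeans(x)
  ord <- order(rownames(x), -m)
  x <- x[ord, , drop = FALSE]
  x[!duplicated(rownames(x)), , drop = FALSE]
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: feature ids in a `feature_id` first column,
#' sample ids as the header.
#'
#' @param x numeric matrix, features x samples.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  write_tsv_matrix(x, path)
}

#' Construct a sample table
#'
#' @param sample_id character vector of unique sample ids.
#' @param group `"control"` or `"case"` per sample.
#' @param batch batch/cohort label per sample.
#' @param excluded logical; samples dropped before any analysis (e.g. patients
#'   under an intervention known to mask the case signal).
#' @param exclusion_reason free-text tag, `""` when not excluded.
#' @return data.frame with the five columns above.
#' @export
sample_table <- function(sample_id, group, batch = "batch1",
                         excluded = FALSE, exclusion_reason = "") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop_cf("duplicate sample ids in sample table")
  group <- as.character(group)
  if (!all(group %in% c("control", "case")))
    stop_cf("group must be 'control' or 'case'")
  data.frame(sample_id = sample_id,
             group = group,
             batch = rep_len(as.character(batch), length(sample_id)),
             excluded = rep_len(as.logical(excluded), length(sample_id)),
             exclusion_reason = rep_len(as.character(exclusion_reason),
                                        length(sample_id)),
             stringsAsFactors = FALSE)
}

check_sample_table <- function(x, samples) {
  if (!setequal(colnames(x), samples$sample_id))
    stop_cf("matrix sample ids and sample table disagree")
  samples[match(colnames(x), samples$sample_id), , drop = FALSE]
}

#' Merge expression cohorts on shared features
#'
#' Features are intersected across cohorts, samples concatenated, and the
#' source cohort recorded as the batch label. Samples flagged `excluded` in
#' their sample table are dropped here.
#'
#' @param matrices list of >= 2 expression matrices with disjoint sample ids.
#' @param tables list of matching sample tables (same length/order).
#' @param cohort_names batch labels, default `cohort1`, `cohort2`, ...
#' @return list with elements `x` (merged matrix) and `samples` (merged table).
#' @export
merge_cohorts <- function(matrices, tables,
                          cohort_names = paste0("cohort", seq_along(matrices))) {
  if (length(matrices) < 2L) stop_cf("merge requires at least two cohorts")
  if (length(tables) != length(matrices)) stop_cf("one sample table per matrix required")
  all_ids <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(all_ids)) stop_cf("sample id sets must be disjoint across cohorts")
  feats <- Reduce(intersect, lapply(matrices, rownames))
  if (length(feats) == 0L) stop_cf("merge error: empty feature intersection")
  kept_mats <- vector("list", length(matrices))
  kept_tabs <- vector("list", length(matrices))
  for (i in seq_along(matrices)) {
    tab <- check_sample_table(matrices[[i]], tables[[i]])
    keep <- !tab$excluded
    if (!any(keep)) stop_cf("merge error: no usable samples in %s", cohort_names[i])
    tab <- tab[keep, , drop = FALSE]
    tab$batch <- cohort_names[i]
    kept_tabs[[i]] <- tab
    kept_mats[[i]] <- matrices[[i]][feats, tab$sample_id, drop = FALSE]
  }
  samples <- do.call(rbind, kept_tabs)
  rownames(samples) <- NULL
  list(x = do.call(cbind, kept_mats), samples = samples)
}

#' Remove additive batch effects while preserving group structure
#'
#' Fits, per feature, a linear model with group and batch covariates and
#' subtracts only the fitted batch component, so that group-associated signal
#' is untouched. With a single batch the input is returned unchanged. Batch
#' perfectly confounded with group is refused, since the batch component is
#' then not identifiable separately from the group effect.
#'
#' @param x expression matrix, features x samples.
#' @param samples sample table covering the columns of `x`.
#' @return matrix of the same shape with batch means aligned within group.
#' @export
remove_batch_effect <- function(x, samples) {
  samples <- check_sample_table(x, samples)
  batch <- factor(samples$batch)
  if (nlevels(batch) < 2L) return(x)
  group <- factor(samples$group, levels = c("control", "case"))
  mm <- model.matrix(~ group + batch)
  if (qr(mm)$rank < ncol(mm)) stop_cf("batch confounded with group")
  design <- model.matrix(~ group)
  out <- limma::removeBatchEffect(x, batch = batch, design = design)
  if (!all(is.finite(out))) stop_cf("batch removal produced non-finite values")
  dimnames(out) <- dimnames(x)
  out
}
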