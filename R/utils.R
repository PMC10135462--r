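# Shared internal helpers: argument checking, id canonicalization, TSV dialect.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cf <- function(...) stop(sprintf(...), call. = FALSE)
warn_cf <- function(...) warning(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min)
    stop_cf("'%s' must be a single integer >= %d (got %s)", name, min,
            paste(format(x), collapse = ","))
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lo || x > hi)
    stop_cf("'%s' must be a single number in [%g, %g]", name, lo, hi)
  as.numeric(x)
}

check_number <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min)
    stop_cf("'%s' must be a single number >= %g", name, min)
  as.numeric(x)
}

#' Canonicalize miRNA identifiers
#'
#' Trims whitespace and normalizes the case of the "miR"/"let" infix in
#' `hsa-miR-...` style identifiers so that edge lists from databases with
#' inconsistent casing can be intersected. `-3p`/`-5p` suffixes are preserved.
#'
#' @param ids character vector of miRNA identifiers.
#' @return character vector of canonical identifiers.
#' @examples
#' canonicalize_mirna_id(c(" hsa-mir-455-3p", "HSA-MIR-21-5p"))
#' @export
canonicalize_mirna_id <- function(ids) {
  ids <- trimws(as.character(ids))
  # species prefix lower-case, 'miR' infix canonical camel case
  ids <- sub("^([A-Za-z]{3})-", "\\L\\1-", ids, perl = TRUE)
  ids <- sub("-(mir|MIR|MiR|mIR)-", "-miR-", ids)
  ids <- sub("-(LET|Let)-", "-let-", ids)
  ids
}

# strict numeric TSV writer shared by the export helpers
write_tsv_matrix <- function(x, path, id_col = "feature_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv_df <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_df <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
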