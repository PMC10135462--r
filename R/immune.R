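# Single-sample gene-set enrichment (ssGSEA) immune scoring, Spearman
# correlation of hub genes with cell-type scores, and two-group score
# comparisons.
#
# The per-sample score for a gene set S is a rank-weighted running-sum
# statistic: genes are ranked by expression within the sample (average ranks
# for ties, highest expression = rank N), the ranked list is walked in
# descending order, and the in-set cumulative distribution weighted by
# rank^alpha is accumulated against the uniform out-of-set cumulative
# distribution; the score is the sum of the running difference. Because only
# ranks enter, scores are invariant to any strictly monotone transform of a
# sample's expression.

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name <tab> description <tab> member...`.
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
  } else {
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    sets <- lapply(lines, function(x) x[-(1:2)])
    names(sets) <- vapply(lines, `[`, character(1), 1L)
  }
  if (anyDuplicated(names(sets))) stop_cf("duplicate gene-set names in %s", path)
  if (any(lengths(sets) == 0L)) stop_cf("empty gene set in %s", path)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], rep_len(description, length(sets))[i], sets[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' ssGSEA enrichment scores
#'
#' @param x expression matrix (log2), features x samples.
#' @param sets named list of gene sets; each must have at least one member in
#'   `x` (an error names any set with none; a warning flags sets with < 25%
#'   of members present).
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize min-max normalize the full score matrix to `[0, 1]`
#'   (default `TRUE`).
#' @return matrix of scores, gene sets x samples, with attributes `alpha` and
#'   `method = "ssgsea"`.
#' @export
ssgsea_scores <- function(x, sets, alpha = 0.25, normalize = TRUE) {
  alpha <- check_number(alpha, "alpha", min = 0)
  if (length(sets) == 0L) stop_cf("no gene sets supplied")
  present <- lapply(sets, intersect, y = rownames(x))
  none <- names(sets)[lengths(present) == 0L]
  if (length(none))
    stop_cf("gene set(s) with no genes in the matrix: %s", paste(none, collapse = ", "))
  frac <- lengths(present) / lengths(sets)
  if (any(frac < 0.25))
    warn_cf("gene set(s) with < 25%% of members present: %s",
            paste(names(sets)[frac < 0.25], collapse = ", "))
  n_genes <- nrow(x)
  scores <- matrix(NA_real_, length(sets), ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    rw <- r[ord]^alpha
    for (s in seq_along(sets)) {
      inset <- rownames(x)[ord] %in% present[[s]]
      in_cdf <- cumsum(rw * inset) / sum(rw[inset])
      out_cdf <- cumsum(!inset) / (n_genes - sum(inset))
      scores[s, j] <- sum(in_cdf - out_cdf)
    }
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1]) / diff(rng)
  }
  attr(scores, "alpha") <- alpha
  attr(scores, "method") <- "ssgsea"
  scores
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-corrected ranks (Pearson correlation of average ranks); p-value from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df, or by exact
#' permutation enumeration when `exact = TRUE` (intended for n <= 10).
#'
#' @param x,y paired numeric vectors.
#' @param exact use exact permutation enumeration of all `n!` rank orders.
#' @return list `rho`, `p`, `degenerate` (constant input).
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = 0, p = 1, degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  n <- length(x)
  if (exact) {
    if (n > 10L) stop_cf("exact permutation p only supported for n <= 10")
    perms <- permutations_of(n)
    null_rho <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    p <- cor_t_pvalue(rho, n)
  }
  list(rho = rho, p = p, degenerate = FALSE)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Correlate hub genes with immune scores
#'
#' Spearman correlation of each hub gene's expression with each cell-type
#' score vector across shared samples.
#'
#' @param x expression matrix.
#' @param hub_mrnas hub gene ids (must be rows of `x`).
#' @param scores a score matrix from [ssgsea_scores()].
#' @return data.frame `gene`, `cell_type`, `rho`, `p`, `degenerate`.
#' @export
correlate_hub_scores <- function(x, hub_mrnas, scores) {
  missing <- setdiff(hub_mrnas, rownames(x))
  if (length(missing))
    stop_cf("hub gene(s) absent from matrix: %s", paste(missing, collapse = ", "))
  ids <- intersect(colnames(x), colnames(scores))
  if (length(ids) < 3L) stop_cf("need >= 3 shared samples")
  grid <- expand.grid(gene = hub_mrnas, cell_type = rownames(scores),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i)
    spearman_cor(x[grid$gene[i], ids], scores[grid$cell_type[i], ids]))
  grid$rho <- vapply(res, `[[`, numeric(1), "rho")
  grid$p <- vapply(res, `[[`, numeric(1), "p")
  grid$degenerate <- vapply(res, `[[`, logical(1), "degenerate")
  grid
}

#' Two-sided Mann-Whitney U test
#'
#' Reports `U = min(U1, U2)`. The p-value is computed by exact enumeration of
#' all group assignments when both groups have <= 8 observations and there
#' are no ties, and by the tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric samples for the two groups.
#' @return list `u`, `p`, `method`.
#' @export
mann_whitney_u <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop_cf("both groups must be non-empty")
  r <- rank(c(a, b), ties.method = "average")
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- anyDuplicated(c(a, b)) > 0L
  if (!ties && n1 <= 8L && n2 <= 8L) {
    # exact: distribution of U over all C(n1+n2, n1) assignments
    combs <- combn(n1 + n2, n1)
    us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    us <- pmin(us, n1 * n2 - us)
    p <- mean(us <= u + 1e-12)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1))
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
    if (sigma2 <= 0) return(list(u = u, p = 1, method = "degenerate"))
    z <- (abs(u1 - mu) - 0.5) / sqrt(sigma2)  # continuity-corrected
    z <- max(z, 0)
    p <- min(1, 2 * pnorm(-z))
    method <- "normal"
  }
  list(u = u, p = p, method = method)
}

#' Compare immune scores between groups
#'
#' Two-sided Mann-Whitney test per cell type, with the median case-control
#' score difference as the direction indicator.
#'
#' @param scores score matrix from [ssgsea_scores()].
#' @param samples sample table covering the score columns.
#' @return data.frame `cell_type`, `u`, `p`, `delta_median` (case - control).
#' @export
compare_groups <- function(scores, samples) {
  samples <- samples[match(colnames(scores), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop_cf("sample table does not cover score columns")
  is_case <- samples$group == "case"
  if (!any(is_case) || !any(!is_case)) stop_cf("both groups required")
  out <- data.frame(cell_type = rownames(scores), u = NA_real_, p = NA_real_,
                    delta_median = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(scores))) {
    res <- mann_whitney_u(scores[i, is_case], scores[i, !is_case])
    out$u[i] <- res$u
    out$p[i] <- res$p
    out$delta_median[i] <- stats::median(scores[i, is_case]) -
      stats::median(scores[i, !is_case])
  }
  out
}
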