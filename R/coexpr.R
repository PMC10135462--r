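# Weighted co-expression analysis: variance filtering, sample outlier
# detection, soft-threshold selection against scale-free topology, the
# topological overlap matrix (TOM), tree-cut module detection with eigengene
# merging, module-trait statistics, and the intersection of modules with
# differential-expression calls.
#
# The network is unsigned: adjacency a_ij = |cor(i,j)|^beta with Pearson
# correlation. The gene tree is built on 1 - TOM; Euclidean distance is used
# only for sample outlier detection.

#' Keep the most variable features
#'
#' Retains the top `ceiling(fraction * n)` features by descending sample
#' variance; ties are broken by feature id ascending so the cut is
#' deterministic. Row order of the surviving features is preserved.
#'
#' @param x expression matrix, features x samples.
#' @param fraction proportion of features to keep, in (0, 1].
#' @return the filtered matrix.
#' @export
select_top_variance <- function(x, fraction) {
  fraction <- check_fraction(fraction, "fraction")
  if (fraction <= 0) stop_cf("'fraction' must be positive")
  v <- apply(x, 1, var)
  k <- ceiling(fraction * nrow(x))
  ord <- order(-v, rownames(x))
  keep <- sort(ord[seq_len(k)])
  x[keep, , drop = FALSE]
}

#' Flag outlier samples by hierarchical clustering
#'
#' Samples are clustered with average linkage on Euclidean distances between
#' their expression profiles; the tree is cut at `cut_height` and every sample
#' outside the largest resulting cluster is flagged.
#'
#' @param x expression matrix, features x samples (>= 3 samples).
#' @param cut_height static cut height on the sample dendrogram.
#' @return character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(x, cut_height) {
  if (ncol(x) < 3L) stop_cf("need >= 3 samples for outlier detection")
  h <- hclust(dist(t(x)), method = "average")
  if (is.infinite(cut_height) || cut_height >= max(h$height)) return(character(0))
  cl <- cutree(h, h = cut_height)
  sizes <- table(cl)
  main <- as.integer(names(sizes)[which.max(sizes)])
  colnames(x)[cl != main]
}

#' Select the soft-thresholding power for scale-free topology
#'
#' For each candidate power the unsigned adjacency `|cor|^beta` is formed, the
#' connectivity `k_i` computed, and the scale-free fit measured by regressing
#' `log10` bin frequency on `log10` mean bin connectivity over `n_bins`
#' equal-count bins. The signed fit index is `-sign(slope) * R^2`, positive
#' when connectivity follows the decaying power law. The selected power is the
#' smallest one reaching `r2_target`; when none does, the power with the best
#' fit is returned with a warning.
#'
#' @param x expression matrix, features x samples.
#' @param powers integer powers to scan.
#' @param r2_target signed R^2 required to accept a power (default 0.85).
#' @param n_bins connectivity bins for the fit (default 10).
#' @return list of class `soft_threshold_report`: `fit` (data.frame with
#'   `power`, `r_squared_signed`, `mean_connectivity`), `power` (selected),
#'   `reached_target` (logical).
#' @export
pick_soft_threshold <- function(x, powers = c(1:10, seq(12, 20, 2)),
                                r2_target = 0.85, n_bins = 10) {
  if (length(powers) == 0L) stop_cf("'powers' must be non-empty")
  powers <- sort(unique(as.integer(powers)))
  ac <- abs(cor(t(x)))
  diag(ac) <- 0
  fit <- data.frame(power = powers, r_squared_signed = NA_real_,
                    mean_connectivity = NA_real_)
  for (i in seq_along(powers)) {
    a <- ac^powers[i]
    k <- colSums(a)
    fit$mean_connectivity[i] <- mean(k)
    fit$r_squared_signed[i] <- tryCatch(scale_free_fit(k, n_bins),
                                        error = function(e) NA_real_)
  }
  ok <- which(!is.na(fit$r_squared_signed) & fit$r_squared_signed >= r2_target)
  if (length(ok)) {
    power <- powers[ok[1]]
    reached <- TRUE
  } else {
    if (all(is.na(fit$r_squared_signed)))
      stop_cf("scale-free fit failed for every candidate power")
    power <- powers[which.max(fit$r_squared_signed)]
    reached <- FALSE
    warn_cf("no power reached signed R^2 >= %g; using best power %d", r2_target, power)
  }
  structure(list(fit = fit, power = power, reached_target = reached,
                 r2_target = r2_target),
            class = "soft_threshold_report")
}

# Scale-free topology fit: the connectivity distribution is summarized over
# equal-count bins and the empirical log density (bin count / bin width) is
# regressed on the log mean bin connectivity. Equal-count bins keep every
# point of the fit equally supported; the density correction is what makes
# them informative (raw counts are constant by construction).
scale_free_fit <- function(k, n_bins) {
  brk <- unique(quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brk) < 3L) stop_cf("fewer than 2 occupied connectivity bins")
  bins <- cut(k, breaks = brk, include.lowest = TRUE)
  freq <- tapply(k, bins, length)
  mk <- tapply(k, bins, mean)
  width <- diff(brk)
  keep <- !is.na(freq) & freq > 0 & mk > 0 & width > 0
  if (sum(keep) < 2L) stop_cf("fewer than 2 occupied connectivity bins")
  lx <- log10(mk[keep]); ly <- log10(freq[keep] / width[keep])
  if (sd(lx) == 0 || sd(ly) == 0) return(0)
  r <- cor(lx, ly)
  -sign(r) * r^2
}

#' @export
print.soft_threshold_report <- function(x, ...) {
  cat(sprintf("Soft threshold scan: selected beta = %d (target R^2 %s %g)\n",
              x$power, if (x$reached_target) ">=" else "not reached,", x$r2_target))
  print(x$fit, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Topological overlap matrix
#'
#' Unsigned adjacency `a_ij = |cor(i,j)|^beta` (diagonal set to 0 for
#' connectivity), then
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j` and `TOM_ii = 1`. Values lie in `[0, 1]`; high overlap means the
#' two genes share neighbours as well as a direct connection.
#'
#' @param x expression matrix, features x samples (>= 3 features).
#' @param beta soft-thresholding power.
#' @return symmetric features x features matrix.
#' @export
compute_tom <- function(x, beta) {
  if (nrow(x) < 3L) stop_cf("TOM needs >= 3 genes")
  beta <- check_number(beta, "beta", min = 1)
  v <- apply(x, 1, var)
  if (any(v == 0))
    stop_cf("zero-variance gene(s): %s",
            paste(head(rownames(x)[v == 0], 5), collapse = ", "))
  a <- abs(cor(t(x)))^beta
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- list(rownames(x), rownames(x))
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut statically at
#' `cut_height` (default: 0.99 of the tree's maximum merge height — the
#' "tree" variant of the dynamic cut, which separates the late
#' module-versus-background joins while keeping branches whole). Each
#' resulting cluster is then recursively re-cut on its own subtree, and a
#' split is accepted only when it produces two or more size-valid submodules
#' whose eigengene dissimilarity `1 - cor` is at least `merge_cut_height`
#' (the merge criterion applied symmetrically), so correlated modules that
#' the single static cut leaves fused are separated without ever creating
#' modules the merge step would immediately undo. Clusters
#' below `min_module_size` are
#' assigned to the unclustered `"grey"` pool. Each surviving module gets an
#' eigengene — the first principal component of its standardized expression,
#' unit norm, oriented so it correlates positively with the module's mean
#' profile — and modules whose eigengene dissimilarity `1 - cor` falls below
#' `merge_cut_height` are merged iteratively. Modules are labelled `M1`,
#' `M2`, ... by decreasing size.
#'
#' @param tom square symmetric similarity matrix from [compute_tom()].
#' @param x the expression matrix the TOM was computed from (needed for
#'   eigengenes), same feature set and order.
#' @param min_module_size minimum genes per module (default 50).
#' @param merge_cut_height eigengene dissimilarity below which modules merge
#'   (default 0.15).
#' @param cut_height static tree cut height; `NULL` for the default
#'   `0.99 * max(merge height)`.
#' @return object of class `module_assignment`: `module` (named gene ->
#'   label vector, `"grey"` = unassigned), `eigengenes` (samples x modules),
#'   `tree` (the hclust object), `cut_height`, plus `MM`/`GS` slots filled by
#'   [gene_stats()].
#' @export
detect_modules <- function(tom, x, min_module_size = 50, merge_cut_height = 0.15,
                           cut_height = NULL) {
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom))
  if (!isTRUE(all.equal(tom, t(tom), tolerance = 1e-8)))
    stop_cf("TOM must be symmetric")
  if (!identical(rownames(tom), rownames(x)))
    stop_cf("TOM and expression matrix feature sets disagree")
  min_module_size <- check_count(min_module_size, "min_module_size")
  h <- hclust(as.dist(1 - tom), method = "average")
  if (is.null(cut_height)) cut_height <- 0.99 * max(h$height)
  cl <- cutree(h, h = cut_height)
  genes <- rownames(tom)
  sizes <- table(cl)
  keep_cl <- as.integer(names(sizes)[sizes >= min_module_size])
  module <- rep("grey", length(genes))
  names(module) <- genes
  if (length(keep_cl) == 0L) {
    warn_cf("all genes unassigned (grey): no cluster reached min_module_size = %d",
            min_module_size)
    return(structure(list(module = module,
                          eigengenes = matrix(numeric(0), ncol(x), 0,
                                              dimnames = list(colnames(x), NULL)),
                          tree = h, cut_height = cut_height, MM = NULL, GS = NULL),
                     class = "module_assignment"))
  }
  groups <- lapply(keep_cl, function(ci) genes[cl == ci])
  groups <- unlist(lapply(groups, split_cluster, tom = tom, x = x,
                          min_module_size = min_module_size,
                          merge_cut_height = merge_cut_height),
                   recursive = FALSE)
  me <- vapply(groups, function(g) module_eigengene(x[g, , drop = FALSE]),
               numeric(ncol(x)))

  # iterative eigengene merge
  repeat {
    if (length(groups) < 2L) break
    cc <- cor(me)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (1 - max(cc) >= merge_cut_height) break
    i <- min(top); j <- max(top)
    groups[[i]] <- c(groups[[i]], groups[[j]])
    groups[[j]] <- NULL
    me <- vapply(groups, function(g) module_eigengene(x[g, , drop = FALSE]),
                 numeric(ncol(x)))
  }

  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, function(g) min(g), character(1)))
  groups <- groups[ord]
  me <- me[, ord, drop = FALSE]
  labels <- paste0("M", seq_along(groups))
  for (i in seq_along(groups)) module[groups[[i]]] <- labels[i]
  colnames(me) <- labels
  rownames(me) <- colnames(x)
  structure(list(module = module, eigengenes = me, tree = h,
                 cut_height = cut_height, MM = NULL, GS = NULL),
            class = "module_assignment")
}

# Recursive refinement of one cluster: re-cut its subtree; accept the split
# only if >= 2 submodules reach min_module_size and every submodule pair is
# separated by at least merge_cut_height in eigengene dissimilarity. Genes
# falling outside the accepted submodules return to the unassigned pool.
split_cluster <- function(g, tom, x, min_module_size, merge_cut_height) {
  if (length(g) < 2 * min_module_size) return(list(g))
  subh <- hclust(as.dist(1 - tom[g, g, drop = FALSE]), method = "average")
  cl <- cutree(subh, h = 0.99 * max(subh$height))
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  if (length(keep) < 2L) return(list(g))
  subs <- lapply(keep, function(ci) g[cl == ci])
  me <- vapply(subs, function(s) module_eigengene(x[s, , drop = FALSE]),
               numeric(ncol(x)))
  cc <- cor(me)
  if (min(1 - cc[upper.tri(cc)]) < merge_cut_height) return(list(g))
  unlist(lapply(subs, split_cluster, tom = tom, x = x,
                min_module_size = min_module_size,
                merge_cut_height = merge_cut_height),
         recursive = FALSE)
}

# first PC of the standardized module expression, unit norm, sign-oriented
# towards the module mean profile
module_eigengene <- function(xm) {
  xs <- t(scale(t(xm)))
  xs[!is.finite(xs)] <- 0
  sv <- svd(xs, nu = 0, nv = 1)
  v <- sv$v[, 1]
  ref <- colMeans(xs)
  if (sum(v * ref) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- sort(table(x$module), decreasing = TRUE)
  cat(sprintf("Module assignment: %d genes, %d modules (+grey)\n",
              length(x$module), ncol(x$eigengenes)))
  print(tab)
  invisible(x)
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with the binary trait
#' (control = 0, case = 1), with the p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df. A constant eigengene is
#' reported as `r = 0` with the `degenerate` flag set.
#'
#' @param assign a `module_assignment`.
#' @param samples sample table matching the eigengene rows.
#' @return data.frame with `module`, `r`, `p`, `degenerate`.
#' @export
module_trait <- function(assign, samples) {
  trait <- trait_vector(assign$eigengenes, samples)
  n <- length(trait)
  out <- data.frame(module = colnames(assign$eigengenes),
                    r = NA_real_, p = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(assign$eigengenes))) {
    e <- assign$eigengenes[, i]
    if (sd(e) == 0 || sd(trait) == 0) {
      out$r[i] <- 0; out$p[i] <- 1; out$degenerate[i] <- TRUE
    } else {
      r <- cor(e, trait)
      out$r[i] <- r
      out$p[i] <- cor_t_pvalue(r, n)
    }
  }
  out
}

trait_vector <- function(me, samples) {
  ids <- rownames(me)
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop_cf("sample table does not cover eigengene samples")
  as.numeric(samples$group == "case")
}

cor_t_pvalue <- function(r, n) {
  r <- min(max(r, -1), 1)
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tt), df = n - 2)
}

#' Module membership and gene significance
#'
#' Fills the `MM` slot (gene x module Pearson correlation with each
#' eigengene) and the `GS` slot (gene correlation with the 0/1 trait) of a
#' module assignment.
#'
#' @param assign a `module_assignment` with eigengenes.
#' @param x the expression matrix used for module detection.
#' @param samples sample table.
#' @return the updated `module_assignment`.
#' @export
gene_stats <- function(assign, x, samples) {
  if (ncol(assign$eigengenes) == 0L) stop_cf("no eigengenes computed")
  trait <- trait_vector(assign$eigengenes, samples)
  xt <- t(x[names(assign$module), rownames(assign$eigengenes), drop = FALSE])
  assign$MM <- cor(xt, assign$eigengenes)
  gs <- as.vector(cor(xt, trait))
  names(gs) <- names(assign$module)
  assign$GS <- gs
  assign
}

#' Disease-specific genes: DE calls intersected with selected modules
#'
#' @param de a thresholded `de_table`.
#' @param assign a `module_assignment`.
#' @param modules module labels to intersect with (must exist).
#' @return sorted character vector of feature ids with a non-`ns` direction
#'   that fall in one of the selected modules.
#' @export
disease_specific_genes <- function(de, assign, modules) {
  known <- unique(assign$module)
  bad <- setdiff(modules, known)
  if (length(bad)) stop_cf("unknown module label(s): %s", paste(bad, collapse = ", "))
  de_ids <- de$feature_id[de$direction != "ns"]
  mod_ids <- names(assign$module)[assign$module %in% modules]
  sort(intersect(de_ids, mod_ids))
}
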