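# Two-group differential expression with empirical-Bayes variance moderation.
#
# Per feature g with group sizes n1 (control) and n2 (case):
#   log2FC_g = mean(case) - mean(control)
#   s2_g     = pooled two-sample variance, d = n1 + n2 - 2 df
# The residual variances are shrunk towards a common prior: the prior df d0
# and scale s0^2 are estimated by moment matching on log s2_g (Smyth's
# scaled-F model), giving the moderated variance
#   s~2_g = (d0 * s0^2 + d * s2_g) / (d0 + d)
# and t_mod = log2FC / (s~ * sqrt(1/n1 + 1/n2)) on d0 + d df
# (d0 = Inf collapses to the normal-theory limit, d0 = 0 to the ordinary t).

#' Moderated two-group differential expression
#'
#' Computes per-feature log2 fold changes (case minus control), moderated
#' t-statistics with an empirical-Bayes variance prior, two-sided p-values and
#' Benjamini-Hochberg adjusted p-values. Direction calls are `"ns"` until
#' [apply_thresholds()] is applied.
#'
#' @param x expression matrix (log2), features x samples, no missing values.
#' @param samples sample table with `group` in `control`/`case`; >= 2 samples
#'   per group required.
#' @param d0 prior degrees of freedom: `NULL` (default) estimates `d0` and
#'   `s0^2` by moment matching; `0` gives the ordinary pooled t; `Inf` the
#'   normal-theory limit with the common prior variance.
#' @return data.frame of class `de_table` with columns `feature_id`, `log2FC`,
#'   `t_mod`, `p_raw`, `p_adj`, `direction`, `degenerate`, sorted by
#'   `feature_id`; attributes `d0` and `s0_sq` carry the fitted prior.
#' @examples
#' x <- matrix(rnorm(200), 20, 10,
#'             dimnames = list(paste0("G", 1:20), paste0("S", 1:10)))
#' st <- sample_table(colnames(x), rep(c("control", "case"), each = 5))
#' de <- moderated_de(x, st)
#' head(de)
#' @export
moderated_de <- function(x, samples, d0 = NULL) {
  samples <- check_sample_table(x, samples)
  if (anyNA(x) || !all(is.finite(x))) stop_cf("expression matrix contains missing values")
  is_case <- samples$group == "case"
  n1 <- sum(!is_case); n2 <- sum(is_case)
  if (n1 < 2L || n2 < 2L) stop_cf("need >= 2 samples per group")
  m_ctl <- rowMeans(x[, !is_case, drop = FALSE])
  m_cas <- rowMeans(x[, is_case, drop = FALSE])
  lfc <- m_cas - m_ctl
  v1 <- apply(x[, !is_case, drop = FALSE], 1, var)
  v2 <- apply(x[, is_case, drop = FALSE], 1, var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  degenerate <- s2 <= 0

  if (is.null(d0)) {
    pri <- fit_variance_prior(s2[!degenerate], d)
    d0_hat <- pri$d0; s0_sq <- pri$s0_sq
  } else {
    d0_hat <- d0
    s0_sq <- if (d0 == 0) 0 else mean(s2[!degenerate])
  }

  if (is.infinite(d0_hat)) {
    s2_mod <- rep(s0_sq, length(s2))
    df_total <- Inf
  } else if (d0_hat == 0) {
    s2_mod <- s2
    df_total <- d
  } else {
    s2_mod <- (d0_hat * s0_sq + d * s2) / (d0_hat + d)
    df_total <- d0_hat + d
  }
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, lfc / se, sign(lfc) * Inf)
  t_mod[se == 0 & lfc == 0] <- 0
  p_raw <- if (is.infinite(df_total)) 2 * pnorm(-abs(t_mod)) else 2 * pt(-abs(t_mod), df = df_total)
  p_raw[is.infinite(t_mod)] <- 0

  out <- data.frame(feature_id = rownames(x), log2FC = lfc, t_mod = t_mod,
                    p_raw = p_raw, p_adj = bh_adjust(p_raw),
                    direction = "ns", degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "d0") <- d0_hat
  attr(out, "s0_sq") <- s0_sq
  attr(out, "df_residual") <- d
  class(out) <- c("de_table", class(out))
  out
}

# Moment matching of a scaled-F model on log sample variances:
#   e_g = log(s2_g) - digamma(d/2) + log(d/2) is an unbiased estimate of
#   log(s0^2) - digamma(d0/2) + log(d0/2) with variance
#   trigamma(d/2) + trigamma(d0/2).
fit_variance_prior <- function(s2, d) {
  s2 <- s2[s2 > 0]
  if (length(s2) < 2L) return(list(d0 = Inf, s0_sq = mean(s2)))
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1L) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of trigamma on (0, Inf); monotone decreasing.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control: with p-values sorted ascending,
#' `q_i = min_{j >= i} p_j * m / j`, capped at 1 and returned in the input
#' order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_cf("p must be numeric")
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop_cf("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Apply fold-change and significance thresholds
#'
#' Direction is `up` when `log2FC > lfc_min` and `p_adj < alpha`, `down` when
#' `log2FC < -lfc_min` and `p_adj < alpha`, else `ns`. Inequalities are
#' strict, so a feature sitting exactly on a threshold is not called.
#'
#' @param de a `de_table` from [moderated_de()].
#' @param lfc_min positive log2 fold-change threshold (0.58 for the mRNA rule,
#'   2 for the miRNA rule in the motivating analysis).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return the `de_table` with the `direction` column filled in.
#' @export
apply_thresholds <- function(de, lfc_min, alpha = 0.05) {
  lfc_min <- check_number(lfc_min, "lfc_min", min = 0)
  alpha <- check_fraction(alpha, "alpha")
  if (lfc_min <= 0 || alpha <= 0) stop_cf("thresholds must be positive")
  dir <- rep("ns", nrow(de))
  sig <- de$p_adj < alpha
  dir[sig & de$log2FC > lfc_min] <- "up"
  dir[sig & de$log2FC < -lfc_min] <- "down"
  de$direction <- dir
  de
}

#' @export
print.de_table <- function(x, ...) {
  n_up <- sum(x$direction == "up"); n_dn <- sum(x$direction == "down")
  cat(sprintf("Differential expression table: %d features (%d up, %d down)\n",
              nrow(x), n_up, n_dn))
  cat(sprintf("  prior df d0 = %.3g, prior variance s0^2 = %.3g\n",
              attr(x, "d0"), attr(x, "s0_sq")))
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
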