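# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# BH step-up straight from the definition: q_i = min_{j: p_j "at or after" i
# in the sorted order} p_(j) * m / j.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# triple-loop TOM
tom_brute <- function(x, beta) {
  a <- abs(cor(t(x)))^beta
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# AUC by explicit pair counting, ties half
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# ssGSEA running sum by an explicit per-position walk
ssgsea_brute_one <- function(expr, set, alpha) {
  r <- rank(expr, ties.method = "average")
  ord <- order(-r)
  N <- length(expr)
  inset <- names(expr)[ord] %in% set
  wsum <- sum(r[names(expr) %in% set]^alpha)
  nin <- sum(inset)
  run_in <- 0; run_out <- 0; total <- 0
  for (pos in seq_len(N)) {
    if (inset[pos]) run_in <- run_in + r[ord[pos]]^alpha / wsum
    else run_out <- run_out + 1 / (N - nin)
    total <- total + (run_in - run_out)
  }
  total
}

# Mann-Whitney min-U by pair counting
mwu_brute <- function(a, b) {
  u1 <- 0
  for (x in a) for (y in b) u1 <- u1 + if (x > y) 1 else if (x == y) 0.5 else 0
  min(u1, length(a) * length(b) - u1)
}

# brute-force triplet enumeration over all node triples
triplets_brute <- function(net) {
  key <- paste(net$edges$mirna_id, net$edges$partner_id, net$edges$partner_class)
  mr <- net$nodes$id[net$nodes$class == "mRNA"]
  mi <- net$nodes$id[net$nodes$class == "miRNA"]
  ln <- net$nodes$id[net$nodes$class == "lncRNA"]
  out <- NULL
  for (g in mr) for (m in mi) for (l in ln)
    if (paste(m, g, "mRNA") %in% key && paste(m, l, "lncRNA") %in% key)
      out <- rbind(out, data.frame(mrna_id = g, mirna_id = m, lncrna_id = l,
                                   stringsAsFactors = FALSE))
  if (is.null(out))
    return(data.frame(mrna_id = character(0), mirna_id = character(0),
                      lncrna_id = character(0)))
  out[order(out$mrna_id, out$mirna_id, out$lncrna_id), , drop = FALSE]
}

degree_brute <- function(net) {
  ids <- net$nodes$id
  vapply(ids, function(i)
    sum(net$edges$mirna_id == i) + sum(net$edges$partner_id == i), integer(1))
}

# random small tripartite network (pairs not necessarily continuous)
random_pairs <- function(n_mrna = 4, n_mirna = 4, n_lnc = 4, n_edges = 10) {
  mp <- unique(data.frame(
    mirna_id = sprintf("m%02d", sample.int(n_mirna, n_edges, replace = TRUE)),
    mrna_id = sprintf("G%02d", sample.int(n_mrna, n_edges, replace = TRUE)),
    stringsAsFactors = FALSE))
  lp <- unique(data.frame(
    mirna_id = sprintf("m%02d", sample.int(n_mirna, n_edges, replace = TRUE)),
    lncrna_id = sprintf("L%02d", sample.int(n_lnc, n_edges, replace = TRUE)),
    stringsAsFactors = FALSE))
  list(mp = mp, lp = lp)
}

rand_expr <- function(n_genes, n_samples, seed = NULL) {
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  x
}

two_group_table <- function(n1, n2) {
  sample_table(c(sprintf("S%02d", seq_len(n1 + n2))),
               rep(c("control", "case"), c(n1, n2)))
}

# first PC of a standardized module block, oriented like the implementation
module_eigengene_oracle <- function(xm) {
  xs <- t(scale(t(xm)))
  pc <- prcomp(t(xs), center = FALSE)$x[, 1]
  pc <- pc / sqrt(sum(pc^2))
  if (sum(pc * colMeans(xs)) < 0) pc <- -pc
  pc
}
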