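test_that("variance filter keeps the top fraction with the stated tie rule", {
  x <- rbind(A = c(0, 0, 2), B = c(0, 0, 4), C = c(0, 0, 6), D = c(0, 0, 8))
  colnames(x) <- c("s1", "s2", "s3")
  expect_identical(rownames(select_top_variance(x, 0.25)), "D")
  expect_identical(select_top_variance(x, 1), x)
  # tie at the cut: lexicographically smaller id wins
  x2 <- rbind(B = c(0, 2), A = c(0, 2), C = c(0, 1))
  colnames(x2) <- c("s1", "s2")
  expect_identical(rownames(select_top_variance(x2, 1 / 3)), "A")
})

test_that("outlier detection flags the offset sample and nothing else", {
  x <- rand_expr(30, 5)
  expect_identical(detect_outlier_samples(x, Inf), character(0))
  x_same <- matrix(1, 10, 4, dimnames = list(paste0("G", 1:10), paste0("S", 1:4)))
  expect_identical(detect_outlier_samples(x_same, 0.5), character(0))
  x[, 3] <- x[, 3] + 100
  # oracle: the offset sample joins last in average-linkage clustering
  h <- hclust(dist(t(x)), method = "average")
  expect_identical(detect_outlier_samples(x, max(h$height) * 0.5), colnames(x)[3])
})

test_that("soft-threshold selection honours the target rule and the single-candidate case", {
  set.seed(5)
  x <- rand_expr(80, 20)
  rep1 <- suppressWarnings(pick_soft_threshold(x, powers = 1))
  expect_identical(rep1$power, 1L)
  # hub-dominated network: one gene correlated with everything
  hub <- rnorm(20)
  xh <- rbind(hub = hub,
              t(vapply(1:30, function(i) 0.95 * hub + rnorm(20, sd = .3 + i / 30),
                       numeric(20))),
              rand_expr(40, 20))
  rownames(xh) <- paste0("G", seq_len(nrow(xh)))
  colnames(xh) <- paste0("S", 1:20)
  rep2 <- suppressWarnings(pick_soft_threshold(xh, powers = 1:6, r2_target = 0.2))
  # selected power is the smallest whose signed R^2 reaches the target
  ok <- which(rep2$fit$r_squared_signed >= 0.2)
  expect_identical(rep2$power, rep2$fit$power[ok[1]])
  # unreachable target exercises the warning + argmax path
  expect_warning(rep3 <- pick_soft_threshold(x, powers = 1:3, r2_target = 0.999),
                 "best power")
  expect_identical(rep3$power,
                   rep3$fit$power[which.max(rep3$fit$r_squared_signed)])
  expect_false(rep3$reached_target)
})

test_that("TOM attains its closed-form values on degenerate networks", {
  # perfectly correlated genes: complete graph, TOM = 1 everywhere
  base <- rnorm(8)
  x <- outer(c(1, 2, 3, 4), base)
  rownames(x) <- paste0("G", 1:4); colnames(x) <- paste0("S", 1:8)
  tom <- compute_tom(x, beta = 6)
  expect_equal(unname(tom), matrix(1, 4, 4), tolerance = 1e-12)
  x[1, ] <- c(1, -1, 1, -1, 1, -1, 1, -1)  # orthogonal to the shared factor
  expect_error(compute_tom(rbind(x, G5 = rep(1, 8)), 6), "zero-variance")
})

test_that("TOM matches the brute-force triple loop on random instances", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(10:20, 1)
    x <- rand_expr(n, sample(6:12, 1))
    beta <- sample(1:8, 1)
    expect_equal(compute_tom(x, beta), tom_brute(x, beta), tolerance = 1e-12)
  }
})

test_that("block-diagonal structure yields pure modules and the size rule greys small ones", {
  set.seed(21)
  n <- 16
  e1 <- rnorm(n); e2 <- rnorm(n)
  x <- rbind(outer(runif(60, 0.8, 1.2), e1), outer(runif(60, 0.8, 1.2), e2))
  x <- x + matrix(rnorm(120 * n, sd = 1e-3), 120, n)
  rownames(x) <- sprintf("G%03d", 1:120); colnames(x) <- sprintf("S%02d", 1:n)
  tom <- compute_tom(x, 6)
  a <- detect_modules(tom, x, min_module_size = 50, merge_cut_height = 0.15)
  expect_identical(ncol(a$eigengenes), 2L)
  m1 <- names(a$module)[a$module == "M1"]
  expect_true(all(m1 %in% sprintf("G%03d", 1:60)) ||
              all(m1 %in% sprintf("G%03d", 61:120)))
  expect_false(any(a$module == "grey"))
  # same blocks but min size above the block size: everything grey
  expect_warning(a2 <- detect_modules(tom, x, min_module_size = 150),
                 "grey")
  expect_true(all(a2$module == "grey"))
  expect_identical(ncol(a2$eigengenes), 0L)
})

test_that("modules with nearly identical eigengenes are merged", {
  set.seed(31)
  n <- 30
  shared <- rnorm(n)
  e1 <- shared + rnorm(n, sd = 0.2)   # cor(e1, e2) ~ 0.96
  e2 <- shared + rnorm(n, sd = 0.2)
  e3 <- rnorm(n)                      # independent module
  x <- rbind(outer(runif(60, .9, 1.1), e1),
             outer(runif(60, .9, 1.1), e2),
             outer(runif(60, .9, 1.1), e3))
  x <- x + matrix(rnorm(180 * n, sd = .05), 180, n)
  rownames(x) <- sprintf("G%03d", 1:180); colnames(x) <- sprintf("S%02d", 1:n)
  tom <- compute_tom(x, 6)
  # cut between the second- and third-highest joins so the tree yields the
  # three planted blocks; the eigengene-merge step then decides the rest
  h <- hclust(as.dist(1 - tom), method = "average")
  hs <- sort(h$height, decreasing = TRUE)
  cut <- mean(hs[2:3])
  no_merge <- detect_modules(tom, x, min_module_size = 50,
                             merge_cut_height = 0.001, cut_height = cut)
  expect_identical(ncol(no_merge$eigengenes), 3L)
  # oracle: whether the correlated blocks merge is decided by eigengene
  # correlation against the merge threshold
  me1 <- module_eigengene_oracle(x[1:60, ])
  me2 <- module_eigengene_oracle(x[61:120, ])
  d <- 1 - cor(me1, me2) * sign(cor(me1, me2))
  expect_lt(d, 0.15)
  merged <- detect_modules(tom, x, min_module_size = 50,
                           merge_cut_height = 0.15, cut_height = cut)
  expect_identical(ncol(merged$eigengenes), 2L)
  big <- names(merged$module)[merged$module == "M1"]
  expect_setequal(big, sprintf("G%03d", 1:120))
})

test_that("eigengenes are unit-norm first principal components", {
  set.seed(41)
  b <- generate_cohort(10, 10, 300, 2, 40, 0, n_triplets = 0, seed = 41)
  tom <- compute_tom(b$mrna[1:80, ], 6)
  a <- detect_modules(tom, b$mrna[1:80, ], min_module_size = 30)
  for (m in colnames(a$eigengenes)) {
    me <- a$eigengenes[, m]
    expect_equal(sum(me^2), 1, tolerance = 1e-10)
    genes <- names(a$module)[a$module == m]
    xs <- t(scale(t(b$mrna[genes, ])))
    pc1 <- prcomp(t(xs), center = FALSE)$x[, 1]
    expect_equal(abs(cor(me, pc1)), 1, tolerance = 1e-8)
    # first-PC optimality: ME explains at least as much variance as any
    # single gene's profile direction
    var_me <- sum((xs %*% me)^2)
    for (g in sample(genes, 5)) {
      dir <- xs[g, ] / sqrt(sum(xs[g, ]^2))
      expect_gte(var_me + 1e-8, sum((xs %*% dir)^2))
    }
  }
})

test_that("module-trait statistics match the closed-form t formula", {
  st <- two_group_table(5, 5)
  trait <- as.numeric(st$group == "case")
  me <- cbind(M1 = trait, M2 = c(1, -1, 1, -1, 0, 0, 1, -1, 1, -1) / 2)
  rownames(me) <- st$sample_id
  assign <- structure(list(module = c(), eigengenes = me), class = "module_assignment")
  mt <- module_trait(assign, st)
  expect_equal(mt$r[1], 1)
  expect_equal(mt$p[1], 0)
  expect_equal(mt$r[2], 0, tolerance = 1e-12)
  expect_equal(mt$p[2], 1, tolerance = 1e-12)
  # published-scale check of the p formula: n = 59, r = 0.53 -> p ~ 2e-5
  r <- 0.53; n <- 59
  p <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  expect_lt(abs(p - 2e-5), 1.5e-5)
  expect_equal(p, 1.7e-5, tolerance = 0.1)
})

test_that("MM and GS equal direct correlation oracles", {
  set.seed(51)
  b <- generate_cohort(8, 8, 200, 2, 30, 0, n_triplets = 0, seed = 51)
  x <- b$mrna[1:60, ]
  a <- detect_modules(compute_tom(x, 6), x, min_module_size = 20)
  a <- gene_stats(a, x, b$samples)
  trait <- as.numeric(b$samples$group == "case")
  for (g in sample(rownames(x), 10)) {
    for (m in colnames(a$eigengenes))
      expect_equal(a$MM[g, m], cor(x[g, ], a$eigengenes[, m]), tolerance = 1e-12)
    expect_equal(a$GS[g], cor(x[g, ], trait), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_true(all(abs(a$MM) <= 1 + 1e-12) && all(abs(a$GS) <= 1 + 1e-12))
})

test_that("disease-specific genes are the DE/module intersection", {
  de <- data.frame(feature_id = c("A", "B", "C", "E"),
                   log2FC = 1, t_mod = 1, p_raw = 0.01, p_adj = 0.01,
                   direction = c("up", "up", "down", "ns"),
                   stringsAsFactors = FALSE)
  assign <- structure(list(module = c(A = "grey", B = "M1", C = "M1",
                                      D = "M1", E = "M2")),
                      class = "module_assignment")
  expect_identical(disease_specific_genes(de, assign, "M1"), c("B", "C"))
  expect_identical(disease_specific_genes(de, assign, c("M1", "M2")), c("B", "C"))
  de_none <- de; de_none$direction <- "ns"
  expect_identical(disease_specific_genes(de_none, assign, "M1"), character(0))
  expect_error(disease_specific_genes(de, assign, "M9"), "unknown module")
})

test_that("planted triplet mRNAs land in detected trait modules and the DE/module funnel", {
  b <- generate_cohort(20, 20, seed = 13)
  xc <- remove_batch_effect(b$mrna, b$samples)
  de <- apply_thresholds(moderated_de(xc, b$samples), 0.58, 0.05)
  xt <- select_top_variance(xc, 0.25)
  sft <- suppressWarnings(pick_soft_threshold(xt))
  a <- detect_modules(compute_tom(xt, sft$power), xt)
  mt <- module_trait(a, b$samples)
  sel <- mt$module[mt$p < 0.05 & mt$r > 0]
  specific <- disease_specific_genes(de, a, sel)
  tri_m <- unique(b$truth$true_triplets$mrna_id)
  expect_true(all(tri_m %in% specific))
})
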