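test_that("generated cohort has the requested shape and a complete truth record", {
  b <- generate_cohort(10, 10, 500, 4, 50, 40, 1.5, 0.5, 2, 0.8, seed = 1)
  expect_identical(dim(b$mrna), c(500L, 20L))
  expect_identical(nrow(b$samples), 20L)
  expect_length(b$truth$de_features[grepl("^G", names(b$truth$de_features))], 40)
  expect_setequal(setdiff(unique(b$truth$module_membership), "background"),
                  paste0("mod", 1:4))
  # every triplet member exists in the matrices / id universe
  tri <- b$truth$true_triplets
  expect_true(all(tri$mrna_id %in% rownames(b$mrna)))
  expect_true(all(tri$mirna_id %in% rownames(b$mirna)))
  expect_true(all(tri$lncrna_id %in% b$truth$lncrna_ids))
  # at least 2 samples per group
  expect_true(all(table(b$samples$group) >= 2))
})

test_that("same seed gives identical bundles, different seed different data", {
  b1 <- generate_cohort(6, 6, 120, 2, 20, 10, 1, 0.4, 2, 0.5, seed = 7)
  b2 <- generate_cohort(6, 6, 120, 2, 20, 10, 1, 0.4, 2, 0.5, seed = 7)
  b3 <- generate_cohort(6, 6, 120, 2, 20, 10, 1, 0.4, 2, 0.5, seed = 8)
  expect_identical(b1$mrna, b2$mrna)
  expect_identical(b1$mirna, b2$mirna)
  expect_identical(b1$truth, b2$truth)
  expect_false(identical(b1$mrna, b3$mrna))
})

test_that("noiseless factor model gives |cor| = 1 within modules and zero group shifts", {
  b <- generate_cohort(8, 8, 200, 2, 30, 10, effect_lfc = 0, noise_sd = 0,
                       n_batches = 1, batch_sd = 0, seed = 3,
                       module_trait_effect = 0, n_triplets = 0)
  for (m in c("mod1", "mod2")) {
    genes <- names(b$truth$module_membership)[b$truth$module_membership == m]
    cc <- cor(t(b$mrna[genes, ]))
    expect_equal(unname(abs(cc)), matrix(1, 30, 30), tolerance = 1e-12)
  }
  grp <- b$samples$group == "case"
  diffs <- rowMeans(b$mrna[, grp]) - rowMeans(b$mrna[, !grp])
  expect_equal(max(abs(diffs)), 0, tolerance = 1e-12)
})

test_that("planted triplets carry the ceRNA sign structure", {
  b <- generate_cohort(10, 10, seed = 5)
  tri <- b$truth$true_triplets
  lfc <- b$truth$de_features
  expect_true(all(lfc[unique(tri$mrna_id)] > 0))
  expect_true(all(lfc[unique(tri$mirna_id)] < 0))
  expect_true(all(b$truth$lncrna_direction[unique(tri$lncrna_id)] == "up"))
})

test_that("interaction tables contain all true edges plus the requested decoys", {
  b <- generate_cohort(8, 8, 300, 2, 30, 20, seed = 2)
  tri <- b$truth$true_triplets
  tabs <- generate_interaction_tables(b$truth, decoy_mrna_edges = 100,
                                      decoy_lncrna_edges = 40,
                                      db_overlap_fraction = 0.5, seed = 4)
  n_true_mrna <- nrow(unique(tri[, c("mirna_id", "mrna_id")]))
  expect_identical(nrow(tabs$mrna_targets), n_true_mrna + 100L)
  key <- function(tab) paste(tab$mirna_id, tab$target_id)
  expect_true(all(paste(tri$mirna_id, tri$mrna_id) %in% key(tabs$mrna_targets)))
  expect_true(all(paste(tri$mirna_id, tri$lncrna_id) %in% key(tabs$lnc_db1)))
  expect_true(all(paste(tri$mirna_id, tri$lncrna_id) %in% key(tabs$lnc_db2)))
})

test_that("with zero overlap the lncRNA-table intersection is exactly the true edges", {
  b <- generate_cohort(8, 8, 300, 2, 30, 20, seed = 2)
  tabs <- generate_interaction_tables(b$truth, 0, 60, db_overlap_fraction = 0,
                                      seed = 9)
  key <- function(tab) paste(tab$mirna_id, tab$target_id)
  inter <- intersect(key(tabs$lnc_db1), key(tabs$lnc_db2))
  tri <- b$truth$true_triplets
  expect_setequal(inter, unique(paste(tri$mirna_id, tri$lncrna_id)))
})

test_that("with full overlap and no decoys the two lncRNA tables are identical", {
  b <- generate_cohort(8, 8, 300, 2, 30, 20, seed = 2)
  tabs <- generate_interaction_tables(b$truth, 0, 0, db_overlap_fraction = 1,
                                      seed = 9)
  expect_identical(tabs$lnc_db1[, c("mirna_id", "target_id")],
                   tabs$lnc_db2[, c("mirna_id", "target_id")])
  tri <- b$truth$true_triplets
  expect_identical(nrow(tabs$lnc_db1),
                   nrow(unique(tri[, c("mirna_id", "lncrna_id")])))
})

test_that("interaction generation refuses an empty truth", {
  b <- generate_cohort(8, 8, 300, 2, 30, 20, n_triplets = 0, seed = 2)
  expect_error(generate_interaction_tables(b$truth), "no triplets")
})

test_that("validation directions reflect planted signs with flip/ns overrides", {
  b <- generate_cohort(8, 8, 300, 2, 30, 20, seed = 2)
  d0 <- generate_validation_directions(b$truth)
  lfc <- b$truth$de_features
  expect_identical(d0$direction[match(names(lfc), d0$node_id)],
                   unname(ifelse(lfc > 0, "up", "down")))
  lnc <- b$truth$lncrna_ids
  d1 <- generate_validation_directions(b$truth, flip_ids = lnc[1], ns_ids = lnc[2])
  expect_identical(d1$direction[d1$node_id == lnc[1]], "down")
  expect_identical(d1$direction[d1$node_id == lnc[2]], "ns")
  other <- setdiff(d1$node_id, lnc[1:2])
  expect_identical(d1$direction[match(other, d1$node_id)],
                   d0$direction[match(other, d0$node_id)])
  expect_error(generate_validation_directions(b$truth, flip_ids = "NOPE"),
               "not in truth")
  expect_error(generate_validation_directions(b$truth, flip_ids = lnc[1],
                                              ns_ids = lnc[1]), "disjoint")
})

test_that("immune sets are planted as recorded and shift = 0 flags nothing", {
  b <- generate_cohort(10, 10, 600, 2, 40, 20, seed = 6)
  b1 <- generate_immune_sets(b, 5, 30, 2, 1.0, seed = 3)
  expect_length(b1$gene_sets, 5)
  expect_true(all(lengths(b1$gene_sets) == 30))
  expect_length(b1$truth$immune_effects, 2)
  # members of shifted sets really moved by +shift in cases only
  is_case <- b1$samples$group == "case"
  g <- b1$gene_sets[[names(b1$truth$immune_effects)[1]]]
  expect_equal(b1$mrna[g, is_case] - b$mrna[g, is_case],
               matrix(1, length(g), sum(is_case),
                      dimnames = dimnames(b$mrna[g, is_case])))
  expect_identical(b1$mrna[g, !is_case], b$mrna[g, !is_case])
  b2 <- generate_immune_sets(b, 5, 30, 2, shift = 0, seed = 3)
  expect_length(b2$truth$immune_effects, 0)
  expect_error(generate_immune_sets(b, 50, 400, 1, 1, seed = 1),
               "exceeds available")
})

test_that("bundle directories round-trip through write/read", {
  b <- generate_cohort(6, 6, 150, 2, 20, 10, seed = 11)
  b$interactions <- generate_interaction_tables(b$truth, 20, 20, 0.5, seed = 1)
  b$directions <- generate_validation_directions(b$truth)
  b <- generate_immune_sets(b, 3, 10, 1, 0.5, seed = 2)
  dir <- tempfile("bundle")
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(b2$mrna, b$mrna, tolerance = 1e-12)
  expect_equal(b2$mirna, b$mirna, tolerance = 1e-12)
  expect_identical(b2$samples$group, b$samples$group)
  expect_identical(b2$interactions$mrna_targets$target_id,
                   b$interactions$mrna_targets$target_id)
  expect_identical(b2$directions, b$directions)
  expect_identical(b2$gene_sets, b$gene_sets)
  expect_identical(unlist(b2$truth$de_features), unlist(b$truth$de_features))
})

test_that("parameter errors are raised before any generation", {
  expect_error(generate_cohort(0, 10), "n_control")
  expect_error(generate_cohort(10, 10, n_genes = 100, n_modules = 4,
                               module_size = 50), "module_size")
  expect_error(generate_cohort(10, 10, n_genes = 100, n_modules = 0,
                               de_count = 200, n_triplets = 0), "de_count")
})
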