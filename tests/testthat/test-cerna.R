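de_stub <- function(ids, dirs) {
  data.frame(feature_id = ids, log2FC = ifelse(dirs == "up", 1, -1),
             t_mod = 0, p_raw = 0.001, p_adj = 0.001, direction = dirs,
             stringsAsFactors = FALSE)
}

test_that("miRNA ids are canonicalized across casing variants", {
  expect_identical(canonicalize_mirna_id(c(" hsa-mir-455-3p", "HSA-MIR-21-5p",
                                           "hsa-miR-3609")),
                   c("hsa-miR-455-3p", "hsa-miR-21-5p", "hsa-miR-3609"))
  t1 <- interaction_table("hsa-mir-455-3p", "XIST", "lncRNA", "db1")
  expect_identical(t1$mirna_id, "hsa-miR-455-3p")
})

test_that("mRNA-miRNA pair filtering applies the opposite-direction rule", {
  targets <- interaction_table(c("m1", "m2", "m3", "m4"),
                               c("G1", "G2", "G3", "G4"), "mRNA")
  de_m <- de_stub(c("G1", "G2", "G3"), c("up", "up", "down"))
  de_mi <- de_stub(c("m1", "m2", "m3", "m4"), c("down", "up", "up", "down"))
  pairs <- build_mrna_mirna_pairs(targets, de_m, de_mi,
                                  specific_mrnas = c("G1", "G2", "G3", "G4"))
  # kept: (m1,G1) up/down. dropped: (m2,G2) both up; (m3,G3) would be
  # down-mRNA polarity; (m4,G4) G4 has no DE call
  expect_identical(pairs, data.frame(mirna_id = "m1", mrna_id = "G1",
                                     stringsAsFactors = FALSE))
  both <- build_mrna_mirna_pairs(targets, de_m, de_mi,
                                 specific_mrnas = c("G1", "G2", "G3", "G4"),
                                 polarity = "both")
  expect_setequal(both$mrna_id, c("G1", "G3"))
  # restriction to the specific set
  none <- build_mrna_mirna_pairs(targets, de_m, de_mi, specific_mrnas = "G2")
  expect_identical(nrow(none), 0L)
  empty <- interaction_table(character(0), character(0), character(0))
  expect_warning(out <- build_mrna_mirna_pairs(empty, de_m, de_mi, "G1"), "empty")
  expect_identical(nrow(out), 0L)
})

test_that("consensus lncRNA pairs are the database intersection", {
  db1 <- interaction_table(c("m1", "m1"), c("L1", "L2"), "lncRNA", "db1")
  db2 <- interaction_table(c("m1", "m1"), c("L2", "L3"), "lncRNA", "db2")
  expect_identical(consensus_lncrna_pairs(db1, db2, "m1"),
                   data.frame(mirna_id = "m1", lncrna_id = "L2",
                              stringsAsFactors = FALSE))
  db3 <- interaction_table("m2", "L9", "lncRNA", "db3")
  expect_identical(nrow(consensus_lncrna_pairs(db1, db3, c("m1", "m2"))), 0L)
  expect_identical(consensus_lncrna_pairs(db1, db1, "m1")$lncrna_id, c("L1", "L2"))
  expect_identical(nrow(consensus_lncrna_pairs(db1, db1, "m7")), 0L)
  mr <- interaction_table("m1", "G1", "mRNA")
  expect_error(consensus_lncrna_pairs(db1, mr, "m1"), "lncRNA")
})

test_that("assembly enforces continuous targeting and computes degrees", {
  mp <- data.frame(mirna_id = c("m1", "m2"), mrna_id = c("G1", "G2"),
                   stringsAsFactors = FALSE)
  lp <- data.frame(mirna_id = "m1", lncrna_id = "L1", stringsAsFactors = FALSE)
  net <- assemble_network(mp, lp)
  # m2/G2 dropped: m2 has no lncRNA partner
  expect_setequal(net$nodes$id, c("m1", "G1", "L1"))
  expect_identical(nrow(net$edges), 2L)
  expect_identical(net$degree[c("m1", "G1", "L1")],
                   c(m1 = 2L, G1 = 1L, L1 = 1L))
  expect_warning(assemble_network(mp[0, ], lp), "no continuous")
})

test_that("assembly and triplet enumeration match brute force on random instances", {
  set.seed(53)
  for (i in 1:30) {
    rp <- random_pairs(n_edges = sample(6:16, 1))
    net <- suppressWarnings(assemble_network(rp$mp, rp$lp))
    # brute-force assembler: keep miRNAs present in both pair lists
    keep <- intersect(rp$mp$mirna_id, rp$lp$mirna_id)
    mp2 <- rp$mp[rp$mp$mirna_id %in% keep, ]
    lp2 <- rp$lp[rp$lp$mirna_id %in% keep, ]
    expect_setequal(net$nodes$id, unique(c(mp2$mirna_id, mp2$mrna_id, lp2$lncrna_id)))
    expect_identical(nrow(net$edges), nrow(mp2) + nrow(lp2))
    expect_identical(unname(net$degree), unname(degree_brute(net)))
    expect_equal(enumerate_triplets(net), triplets_brute(net))
    # bipartiteness: no edge joins two nodes of the same class
    cls <- setNames(net$nodes$class, net$nodes$id)
    expect_true(all(cls[net$edges$mirna_id] == "miRNA"))
    expect_true(all(cls[net$edges$partner_id] != "miRNA"))
  }
})

test_that("triplet enumeration covers products and empty networks", {
  mp <- data.frame(mirna_id = "m1", mrna_id = c("G1", "G2"), stringsAsFactors = FALSE)
  lp <- data.frame(mirna_id = "m1", lncrna_id = c("L1", "L2"), stringsAsFactors = FALSE)
  tri <- enumerate_triplets(assemble_network(mp, lp))
  expect_identical(nrow(tri), 4L)
  no_lnc <- suppressWarnings(assemble_network(mp, lp[0, ]))
  expect_identical(nrow(enumerate_triplets(no_lnc)), 0L)
})

test_that("hub ranking takes top-k by degree with lexicographic ties", {
  mp <- data.frame(mirna_id = "m1", mrna_id = sprintf("G%d", 1:4),
                   stringsAsFactors = FALSE)
  lp <- data.frame(mirna_id = "m1", lncrna_id = sprintf("L%d", 1:4),
                   stringsAsFactors = FALSE)
  net <- assemble_network(mp, lp)   # star centred on m1
  expect_identical(rank_hubs(net, 1)$ranking$id, "m1")
  # all leaves tie at degree 1: lexicographically smallest fill the cut
  top <- rank_hubs(net, 3)$ranking
  expect_identical(top$id, c("m1", "G1", "G2"))
  expect_warning(all_nodes <- rank_hubs(net, 99), "exceeds")
  expect_identical(nrow(all_nodes$ranking), nrow(net$nodes))
  set.seed(59)
  for (i in 1:30) {
    rp <- random_pairs(n_edges = sample(8:14, 1))
    net <- suppressWarnings(assemble_network(rp$mp, rp$lp))
    if (nrow(net$nodes) == 0) next
    k <- sample.int(nrow(net$nodes), 1)
    rk <- rank_hubs(net, k)$ranking
    deg <- degree_brute(net)
    ord <- order(-deg, net$nodes$id)
    expect_identical(rk$id, net$nodes$id[ord][seq_len(k)])
  }
})

test_that("hub subnetworks only contain parent edges among hub nodes", {
  set.seed(61)
  rp <- random_pairs(n_edges = 14)
  net <- suppressWarnings(assemble_network(rp$mp, rp$lp))
  hubs <- rank_hubs(net, min(6, nrow(net$nodes)))
  sub <- hubs$network
  expect_true(all(sub$edges$mirna_id %in% hubs$ranking$id))
  expect_true(all(sub$edges$partner_id %in% hubs$ranking$id))
  parent_keys <- paste(net$edges$mirna_id, net$edges$partner_id)
  expect_true(all(paste(sub$edges$mirna_id, sub$edges$partner_id) %in% parent_keys))
})

test_that("direction pruning keeps only up lncRNAs and re-applies continuity", {
  hub <- load_osa_hub_network()
  pruned <- prune_by_validation(hub$network, hub$directions)
  lnc_left <- pruned$hubs$network$nodes$id[pruned$hubs$network$nodes$class == "lncRNA"]
  expect_identical(sort(lnc_left), c("KCNQ1OT1", "OIP5-AS1", "XIST"))
  expect_setequal(pruned$removed_lncrnas, c("NEAT1", "ZNF561-AS1"))
  expect_identical(nrow(pruned$triplets), 12L)
  # no edges added, node set within the input network
  expect_true(all(pruned$hubs$network$nodes$id %in% hub$network$nodes$id))
  expect_lte(nrow(pruned$hubs$network$edges), nrow(hub$network$edges))
})

test_that("pruning drops everything when no lncRNA is validated up", {
  mp <- data.frame(mirna_id = "m1", mrna_id = "G1", stringsAsFactors = FALSE)
  lp <- data.frame(mirna_id = "m1", lncrna_id = c("L1", "L2"), stringsAsFactors = FALSE)
  net <- assemble_network(mp, lp)
  dirs <- data.frame(node_id = c("L1", "L2"), direction = "ns",
                     stringsAsFactors = FALSE)
  out <- suppressWarnings(prune_by_validation(net, dirs))
  expect_identical(nrow(out$triplets), 0L)
  expect_identical(nrow(out$hubs$network$nodes), 0L)
  expect_error(prune_by_validation(net, dirs[1, ]), "missing validated direction")
})

test_that("end-to-end: planted triplets survive assembly, flipped/ns lncRNAs are pruned out", {
  b <- generate_cohort(22, 22, seed = 67)
  tabs <- generate_interaction_tables(b$truth, 200, 200, 0.3, seed = 67)
  de_m <- apply_thresholds(moderated_de(remove_batch_effect(b$mrna, b$samples),
                                        b$samples), 0.58, 0.05)
  de_mi <- apply_thresholds(moderated_de(b$mirna, b$samples), 2, 0.05)
  tri <- b$truth$true_triplets
  specific <- names(b$truth$de_features)[b$truth$de_features > 0]
  specific <- intersect(specific, rownames(b$mrna))
  pairs_m <- build_mrna_mirna_pairs(tabs$mrna_targets, de_m, de_mi, specific)
  # every true edge kept; decoy edges touching an ns feature dropped
  expect_true(all(paste(tri$mirna_id, tri$mrna_id) %in%
                  paste(pairs_m$mirna_id, pairs_m$mrna_id)))
  ns_feats <- c(de_m$feature_id[de_m$direction == "ns"],
                de_mi$feature_id[de_mi$direction == "ns"])
  expect_false(any(pairs_m$mirna_id %in% ns_feats |
                   pairs_m$mrna_id %in% ns_feats))
  pairs_l <- consensus_lncrna_pairs(tabs$lnc_db1, tabs$lnc_db2,
                                    unique(pairs_m$mirna_id))
  net <- assemble_network(pairs_m, pairs_l)
  found <- enumerate_triplets(net)
  key <- function(d) paste(d$mrna_id, d$mirna_id, d$lncrna_id)
  expect_true(all(key(tri) %in% key(found)))
  # flip one planted lncRNA, mark one ns, everything else validated
  lnc <- b$truth$lncrna_ids
  dirs <- generate_validation_directions(b$truth, flip_ids = lnc[1], ns_ids = lnc[2])
  extra <- setdiff(net$nodes$id[net$nodes$class == "lncRNA"], dirs$node_id)
  dirs <- rbind(dirs, data.frame(node_id = extra, direction = "ns",
                                 stringsAsFactors = FALSE))
  pruned <- prune_by_validation(net, dirs)
  pk <- key(pruned$triplets)
  expect_false(any(pruned$triplets$lncrna_id %in% lnc[1:2]))
  consistent <- tri[!(tri$lncrna_id %in% lnc[1:2]), ]
  expect_true(all(key(consistent) %in% pk))
})
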