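# Seeded synthetic-cohort generator.
#
# Emulates a merged two-group, multi-batch log2 microarray cohort with:
#  - co-expression modules built as latent-factor blocks
#    (gene = loading * module eigenvector + Gaussian noise),
#  - planted differentially expressed genes/miRNAs with signed log2FC shifts,
#  - additive per-feature batch offsets (constant within batch),
#  - planted ceRNA triplets with the ceRNA sign structure
#    (mRNA up, shared miRNA down, lncRNA up),
#  - decoy interaction edges and two partially overlapping lncRNA-target
#    databases whose intersection contains every true edge,
#  - planted immune-signature group shifts.
# lncRNAs carry no expression matrix (they are prediction-only and enter the
# pipeline through interaction tables and a validated direction label), and
# every structure is recorded in a truth record so recovery is checkable.
# All randomness flows through the seed argument via a local RNG scope.

#' Generate a synthetic case/control cohort bundle
#'
#' @param n_control,n_case samples per group.
#' @param n_genes mRNA features.
#' @param n_modules,module_size planted co-expression modules (consecutive
#'   gene blocks; `n_modules * module_size <= n_genes`).
#' @param de_count planted DE mRNAs (60% up, the rest down).
#' @param effect_lfc absolute planted log2 fold change for mRNAs.
#' @param noise_sd per-observation Gaussian noise, log2 units.
#' @param n_batches batches (assigned round-robin within group, so batch is
#'   never confounded with group).
#' @param batch_sd SD of the per-feature additive batch offsets.
#' @param seed integer seed; identical parameters + seed give identical
#'   bundles.
#' @param n_mirnas,mirna_de_count,mirna_effect_lfc miRNA matrix size and
#'   planted miRNA DE (triplet miRNAs are always planted down).
#' @param n_triplets planted ceRNA triplets.
#' @param n_triplet_mirnas miRNAs carrying the triplets; each gets exactly one
#'   mRNA partner (so the per-miRNA mRNA x lncRNA product, which is what
#'   triplet enumeration recovers, equals the planted triplet list).
#' @param n_triplet_lncrnas size of the lncRNA pool the triplets draw from.
#' @param module_trait_effect shift added to the eigenvector of each
#'   trait-associated module in case samples (in eigenvector SD units). The
#'   first `ceiling(n_modules / 2)` modules are trait-associated; the default
#'   1.2 yields eigengene-trait correlations around 0.5, the strength the
#'   pipeline is designed to pick up. Set 0 for a trait-null cohort.
#' @return object of class `cohort_bundle` with elements `mrna`, `mirna`
#'   (matrices), `samples` (sample table), `truth` (truth record),
#'   `gene_sets` (empty until [generate_immune_sets()]), `interactions`,
#'   `directions` (`NULL` until generated).
#' @examples
#' b <- generate_cohort(10, 10, 500, 4, 50, 40, 1.5, 0.5, 2, 0.8, seed = 1)
#' dim(b$mrna)
#' @export
generate_cohort <- function(n_control = 16, n_case = 44, n_genes = 1000,
                            n_modules = 4, module_size = 60, de_count = 86,
                            effect_lfc = 1.5, noise_sd = 0.5, n_batches = 2,
                            batch_sd = 0.8, seed = 1L,
                            n_mirnas = 120, mirna_de_count = 40,
                            mirna_effect_lfc = 2.5, n_triplets = 10,
                            n_triplet_mirnas = 5, n_triplet_lncrnas = 4,
                            module_trait_effect = 1.2) {
  n_control <- check_count(n_control, "n_control", 2L)
  n_case <- check_count(n_case, "n_case", 2L)
  n_genes <- check_count(n_genes, "n_genes")
  n_modules <- check_count(n_modules, "n_modules", 0L)
  module_size <- check_count(module_size, "module_size")
  check_number(module_trait_effect, "module_trait_effect", 0)
  de_count <- check_count(de_count, "de_count", 0L)
  n_batches <- check_count(n_batches, "n_batches")
  n_mirnas <- check_count(n_mirnas, "n_mirnas")
  check_number(effect_lfc, "effect_lfc", 0); check_number(noise_sd, "noise_sd", 0)
  check_number(batch_sd, "batch_sd", 0)
  if (n_modules * module_size > n_genes)
    stop_cf("module_size * n_modules must be <= n_genes")
  if (de_count > n_genes) stop_cf("de_count must be <= n_genes")
  if (mirna_de_count > n_mirnas) stop_cf("mirna_de_count must be <= n_mirnas")
  n_up <- ceiling(de_count * 0.6)
  if (n_triplets > 0) {
    if (n_triplet_mirnas > mirna_de_count || n_triplet_mirnas > n_up)
      stop_cf("not enough planted DE features to host the triplets")
    if (ceiling(n_triplets / n_triplet_mirnas) > n_triplet_lncrnas)
      stop_cf("lncRNA pool too small for the requested triplet count")
  }

  withr::with_seed(seed, {
    n <- n_control + n_case
    sample_ids <- c(sprintf("CTL%02d", seq_len(n_control)),
                    sprintf("CASE%02d", seq_len(n_case)))
    group <- rep(c("control", "case"), c(n_control, n_case))
    batch <- unlist(lapply(c(n_control, n_case), function(m)
      sprintf("batch%d", rep_len(seq_len(n_batches), m))))
    samples <- sample_table(sample_ids, group, batch)

    genes <- sprintf("G%04d", seq_len(n_genes))
    module_membership <- setNames(rep("background", n_genes), genes)
    is_case <- group == "case"
    n_assoc <- if (n_modules > 0 && module_trait_effect > 0) ceiling(n_modules / 2) else 0L
    trait_modules <- if (n_assoc > 0) sprintf("mod%d", seq_len(n_assoc)) else character(0)
    baseline <- runif(n_genes, 6, 12)
    x <- matrix(baseline, n_genes, n, dimnames = list(genes, sample_ids))
    for (m in seq_len(n_modules)) {
      idx <- ((m - 1) * module_size + 1):(m * module_size)
      module_membership[idx] <- sprintf("mod%d", m)
      # factors are centred within group so that group-mean differences come
      # only from planted effects, never from finite-sample factor imbalance
      eig <- rnorm(n)
      eig <- eig - ave(eig, group)
      if (m <= n_assoc) eig <- eig + module_trait_effect * is_case
      # loading floor keeps module-gene variance above that of background DE
      # genes, so the top-variance filter retains whole modules
      loading <- runif(module_size, 0.9, 1.3)
      x[idx, ] <- x[idx, ] + outer(loading, eig)
    }
    if (noise_sd > 0) x <- x + matrix(rnorm(n_genes * n, 0, noise_sd), n_genes, n)

    # planted DE: triplet mRNAs are up-regulated module genes, preferentially
    # inside the trait-associated modules; the remaining DE genes are placed
    # outside the trait-associated modules so that their planted log2FC is
    # not distorted by the module-level group shift
    host_modules <- if (n_assoc > 0) n_assoc else n_modules
    tri_mrnas <- if (n_triplets > 0) {
      picks <- integer(n_triplet_mirnas)
      for (i in seq_len(n_triplet_mirnas)) {
        if (host_modules > 0) {
          m <- ((i - 1) %% host_modules) + 1
          picks[i] <- (m - 1) * module_size + ((i - 1) %/% host_modules) + 1
        } else picks[i] <- i  # no modules: host triplet mRNAs in background genes
      }
      genes[picks]
    } else character(0)
    assoc_genes <- genes[module_membership %in% trait_modules]
    rest <- setdiff(genes, c(tri_mrnas, assoc_genes))
    if (length(rest) < de_count - length(tri_mrnas)) rest <- setdiff(genes, tri_mrnas)
    up_extra <- sample(rest, n_up - length(tri_mrnas))
    up_genes <- c(tri_mrnas, up_extra)
    down_genes <- sample(setdiff(rest, up_extra), de_count - n_up)
    de_lfc <- setNames(c(rep(effect_lfc, length(up_genes)),
                         rep(-effect_lfc, length(down_genes))),
                       c(up_genes, down_genes))
    x[up_genes, is_case] <- x[up_genes, is_case] + effect_lfc
    x[down_genes, is_case] <- x[down_genes, is_case] - effect_lfc

    # batch offsets, batch 1 as reference
    batch_levels <- sprintf("batch%d", seq_len(n_batches))
    batch_offsets <- setNames(vector("list", n_batches), batch_levels)
    batch_offsets[[1]] <- setNames(rep(0, n_genes), genes)
    if (n_batches > 1) for (b in 2:n_batches) {
      off <- rnorm(n_genes, 0, batch_sd)
      batch_offsets[[b]] <- setNames(off, genes)
      cols <- batch == batch_levels[b]
      x[, cols] <- x[, cols] + off
    }

    # miRNA matrix on the same samples
    mirnas <- sprintf("hsa-miR-%04d-5p", seq_len(n_mirnas))
    xm <- matrix(runif(n_mirnas, 4, 10), n_mirnas, n,
                 dimnames = list(mirnas, sample_ids))
    if (noise_sd > 0) xm <- xm + matrix(rnorm(n_mirnas * n, 0, noise_sd), n_mirnas, n)
    tri_mirnas <- mirnas[seq_len(n_triplet_mirnas)]
    other_de <- sample(setdiff(mirnas, tri_mirnas), mirna_de_count - n_triplet_mirnas)
    mir_down <- c(tri_mirnas, other_de[seq_len(floor(length(other_de) / 2))])
    mir_up <- setdiff(other_de, mir_down)
    mir_lfc <- setNames(c(rep(-mirna_effect_lfc, length(mir_down)),
                          rep(mirna_effect_lfc, length(mir_up))),
                        c(mir_down, mir_up))
    xm[mir_down, is_case] <- xm[mir_down, is_case] - mirna_effect_lfc
    xm[mir_up, is_case] <- xm[mir_up, is_case] + mirna_effect_lfc

    # planted triplets: per-miRNA product structure
    true_triplets <- NULL
    lnc_pool <- sprintf("LNC-T%02d", seq_len(n_triplet_lncrnas))
    if (n_triplets > 0) {
      per <- rep(n_triplets %/% n_triplet_mirnas, n_triplet_mirnas)
      extra <- n_triplets %% n_triplet_mirnas
      if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
      true_triplets <- do.call(rbind, lapply(seq_len(n_triplet_mirnas), function(i) {
        if (per[i] == 0) return(NULL)
        lncs <- sample(lnc_pool, per[i])
        data.frame(mrna_id = tri_mrnas[i], mirna_id = tri_mirnas[i],
                   lncrna_id = lncs, stringsAsFactors = FALSE)
      }))
      rownames(true_triplets) <- NULL
    } else {
      true_triplets <- data.frame(mrna_id = character(0), mirna_id = character(0),
                                  lncrna_id = character(0))
    }
    used_lnc <- unique(true_triplets$lncrna_id)

    truth <- list(
      module_membership = module_membership,
      trait_modules = trait_modules,
      de_features = c(de_lfc, mir_lfc),
      true_triplets = true_triplets,
      lncrna_direction = setNames(rep("up", length(used_lnc)), used_lnc),
      immune_effects = setNames(numeric(0), character(0)),
      batch_offsets = batch_offsets,
      mrna_ids = genes, mirna_ids = mirnas, lncrna_ids = used_lnc,
      params = list(n_control = n_control, n_case = n_case, seed = seed,
                    effect_lfc = effect_lfc, noise_sd = noise_sd,
                    batch_sd = batch_sd, mirna_effect_lfc = mirna_effect_lfc))

    structure(list(mrna = x, mirna = xm, samples = samples, truth = truth,
                   interactions = NULL, directions = NULL,
                   gene_sets = list()),
              class = "cohort_bundle")
  })
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("Synthetic cohort bundle: %d genes x %d samples (mRNA), %d miRNAs\n",
              nrow(x$mrna), ncol(x$mrna), nrow(x$mirna)))
  cat(sprintf("  planted: %d modules, %d DE features, %d ceRNA triplets, %d shifted gene sets\n",
              length(setdiff(unique(x$truth$module_membership), "background")),
              length(x$truth$de_features), nrow(x$truth$true_triplets),
              length(x$truth$immune_effects)))
  invisible(x)
}

#' Generate interaction tables with decoys
#'
#' Builds one miRNA->mRNA table containing every true (miRNA, mRNA) edge plus
#' `decoy_mrna_edges` decoys, and two miRNA->lncRNA tables that both contain
#' every true (miRNA, lncRNA) edge; a fraction `db_overlap_fraction` of the
#' lncRNA decoys is shared between the two databases and the remainder is
#' unique per database, so for any overlap fraction the intersection of the
#' two lncRNA tables is exactly the true edges plus the shared decoys.
#'
#' @param truth the truth record of a [generate_cohort()] bundle (non-empty
#'   triplet list required).
#' @param decoy_mrna_edges,decoy_lncrna_edges decoy edge counts (lncRNA count
#'   is per database).
#' @param db_overlap_fraction fraction of lncRNA decoys shared by both
#'   databases, in `[0, 1]`.
#' @param seed integer seed.
#' @return list of `interaction_table`s: `mrna_targets`, `lnc_db1`, `lnc_db2`.
#' @export
generate_interaction_tables <- function(truth, decoy_mrna_edges = 200,
                                        decoy_lncrna_edges = 200,
                                        db_overlap_fraction = 0.3, seed = 1L) {
  if (is.null(truth$true_triplets) || nrow(truth$true_triplets) == 0L)
    stop_cf("generation error: truth contains no triplets")
  db_overlap_fraction <- check_fraction(db_overlap_fraction, "db_overlap_fraction")
  decoy_mrna_edges <- check_count(decoy_mrna_edges, "decoy_mrna_edges", 0L)
  decoy_lncrna_edges <- check_count(decoy_lncrna_edges, "decoy_lncrna_edges", 0L)
  tri <- truth$true_triplets
  true_mrna <- unique(tri[, c("mirna_id", "mrna_id")])
  true_lnc <- unique(tri[, c("mirna_id", "lncrna_id")])

  withr::with_seed(seed, {
    decoy_lnc_pool <- c(truth$lncrna_ids,
                        sprintf("LNC-D%03d", seq_len(max(30, decoy_lncrna_edges %/% 4))))
    mrna_decoys <- sample_decoy_edges(truth$mirna_ids, truth$mrna_ids,
                                      paste(true_mrna$mirna_id, true_mrna$mrna_id),
                                      decoy_mrna_edges)
    n_shared <- round(db_overlap_fraction * decoy_lncrna_edges)
    lnc_decoys <- sample_decoy_edges(truth$mirna_ids, decoy_lnc_pool,
                                     paste(true_lnc$mirna_id, true_lnc$lncrna_id),
                                     n_shared + 2 * (decoy_lncrna_edges - n_shared))
    shared <- head(lnc_decoys, n_shared)
    uniq <- if (nrow(lnc_decoys) > n_shared)
      lnc_decoys[-seq_len(n_shared), , drop = FALSE] else lnc_decoys[0, ]
    half <- nrow(uniq) %/% 2
    db1_edges <- rbind(true_lnc_df(true_lnc), shared, head(uniq, half))
    db2_edges <- rbind(true_lnc_df(true_lnc), shared,
                       if (half > 0) uniq[-seq_len(half), , drop = FALSE] else uniq[0, ])
    list(
      mrna_targets = interaction_table(
        c(true_mrna$mirna_id, mrna_decoys$from),
        c(true_mrna$mrna_id, mrna_decoys$to), "mRNA", "target_db"),
      lnc_db1 = interaction_table(db1_edges$from, db1_edges$to, "lncRNA", "lnc_db1"),
      lnc_db2 = interaction_table(db2_edges$from, db2_edges$to, "lncRNA", "lnc_db2"))
  })
}

true_lnc_df <- function(true_lnc)
  data.frame(from = true_lnc$mirna_id, to = true_lnc$lncrna_id,
             stringsAsFactors = FALSE)

# distinct random (from, to) pairs avoiding a forbidden key set
sample_decoy_edges <- function(from_pool, to_pool, forbidden, n) {
  if (n == 0L) return(data.frame(from = character(0), to = character(0)))
  out <- data.frame(from = character(0), to = character(0))
  guard <- 0L
  while (nrow(out) < n) {
    m <- (n - nrow(out)) * 3L + 10L
    cand <- data.frame(from = sample(from_pool, m, replace = TRUE),
                       to = sample(to_pool, m, replace = TRUE),
                       stringsAsFactors = FALSE)
    cand <- cand[!(paste(cand$from, cand$to) %in% forbidden), , drop = FALSE]
    out <- rbind(out, cand)
    out <- out[!duplicated(paste(out$from, out$to)), , drop = FALSE]
    guard <- guard + 1L
    if (guard > 100L) stop_cf("unable to draw %d distinct decoy edges", n)
  }
  head(out, n)
}

#' Generate a validated-direction table from the truth record
#'
#' Every planted DE feature and lncRNA gets its planted direction;
#' `flip_ids` get the reversed direction and `ns_ids` are labelled
#' not-significant — emulating a wet-lab validation that contradicts or fails
#' to confirm part of the prediction.
#'
#' @param truth truth record.
#' @param flip_ids,ns_ids disjoint id sets to override (must exist in truth).
#' @return data.frame `node_id`, `direction`.
#' @export
generate_validation_directions <- function(truth, flip_ids = character(0),
                                           ns_ids = character(0)) {
  if (length(intersect(flip_ids, ns_ids)))
    stop_cf("flip_ids and ns_ids must be disjoint")
  dirs <- c(ifelse(truth$de_features > 0, "up", "down"),
            truth$lncrna_direction)
  unknown <- setdiff(c(flip_ids, ns_ids), names(dirs))
  if (length(unknown))
    stop_cf("id(s) not in truth: %s", paste(unknown, collapse = ", "))
  dirs[flip_ids] <- ifelse(dirs[flip_ids] == "up", "down", "up")
  dirs[ns_ids] <- "ns"
  data.frame(node_id = names(dirs), direction = unname(dirs),
             stringsAsFactors = FALSE)
}

#' Plant immune gene sets and group shifts into a bundle
#'
#' Draws `n_sets` disjoint gene sets from the non-DE background genes of the
#' cohort and raises the case-group mean of the members of the first
#' `n_shift_sets` sets by `shift` log2 units in the bundle's mRNA matrix.
#' The truth record notes which sets were shifted (none when `shift = 0`).
#'
#' @param bundle a `cohort_bundle`.
#' @param n_sets,set_size number and size of the gene sets.
#' @param n_shift_sets how many sets receive the case shift
#'   (`<= n_sets`).
#' @param shift planted case-group increase, log2 units.
#' @param seed integer seed.
#' @return the bundle with `gene_sets`, a modified `mrna` matrix and
#'   `truth$immune_effects` filled in.
#' @export
generate_immune_sets <- function(bundle, n_sets = 8, set_size = 30,
                                 n_shift_sets = 2, shift = 1.0, seed = 1L) {
  n_sets <- check_count(n_sets, "n_sets")
  set_size <- check_count(set_size, "set_size")
  n_shift_sets <- check_count(n_shift_sets, "n_shift_sets", 0L)
  if (n_shift_sets > n_sets) stop_cf("n_shift_sets must be <= n_sets")
  check_number(shift, "shift", 0)
  truth <- bundle$truth
  candidates <- setdiff(names(truth$module_membership)[truth$module_membership == "background"],
                        names(truth$de_features))
  if (n_sets * set_size > length(candidates))
    stop_cf("set_size exceeds available background gene count")
  withr::with_seed(seed, {
    members <- sample(candidates, n_sets * set_size)
    sets <- split(members, rep(seq_len(n_sets), each = set_size))
    names(sets) <- sprintf("ImmuneSet%02d", seq_len(n_sets))
    shifted <- if (shift > 0 && n_shift_sets > 0) names(sets)[seq_len(n_shift_sets)]
               else character(0)
    is_case <- bundle$samples$group[match(colnames(bundle$mrna),
                                          bundle$samples$sample_id)] == "case"
    for (s in shifted)
      bundle$mrna[sets[[s]], is_case] <- bundle$mrna[sets[[s]], is_case] + shift
    bundle$gene_sets <- sets
    bundle$truth$immune_effects <- setNames(rep(shift, length(shifted)), shifted)
    bundle
  })
}

#' Write / read a cohort bundle directory
#'
#' Serializes the bundle as plain text: `mrna.tsv`, `mirna.tsv`,
#' `samples.tsv`, `targets_mrna.tsv`, `targets_lnc_db1.tsv`,
#' `targets_lnc_db2.tsv`, `directions.tsv`, `immune_sets.gmt`, `truth.json`.
#' Components not yet generated are skipped.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(bundle$mrna, file.path(dir, "mrna.tsv"))
  write_expression(bundle$mirna, file.path(dir, "mirna.tsv"))
  write_tsv_df(bundle$samples, file.path(dir, "samples.tsv"))
  if (!is.null(bundle$interactions)) {
    write_interactions(bundle$interactions$mrna_targets,
                       file.path(dir, "targets_mrna.tsv"))
    write_interactions(bundle$interactions$lnc_db1,
                       file.path(dir, "targets_lnc_db1.tsv"))
    write_interactions(bundle$interactions$lnc_db2,
                       file.path(dir, "targets_lnc_db2.tsv"))
  }
  if (!is.null(bundle$directions))
    write_directions(bundle$directions, file.path(dir, "directions.tsv"))
  if (length(bundle$gene_sets))
    write_gmt(bundle$gene_sets, file.path(dir, "immune_sets.gmt"))
  truth <- bundle$truth
  # jsonlite drops names of atomic vectors; serialize them as objects
  for (f in c("module_membership", "de_features", "lncrna_direction",
              "immune_effects"))
    truth[[f]] <- as.list(truth[[f]])
  truth$batch_offsets <- lapply(truth$batch_offsets, as.list)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth$module_membership <- unlist(truth$module_membership)
  truth$de_features <- unlist(truth$de_features)
  truth$batch_offsets <- lapply(truth$batch_offsets, unlist)
  bundle <- list(
    mrna = read_expression(file.path(dir, "mrna.tsv")),
    mirna = read_expression(file.path(dir, "mirna.tsv")),
    samples = read_tsv_df(file.path(dir, "samples.tsv")),
    truth = truth, interactions = NULL, directions = NULL, gene_sets = list())
  if (file.exists(file.path(dir, "targets_mrna.tsv")))
    bundle$interactions <- list(
      mrna_targets = read_interactions(file.path(dir, "targets_mrna.tsv")),
      lnc_db1 = read_interactions(file.path(dir, "targets_lnc_db1.tsv")),
      lnc_db2 = read_interactions(file.path(dir, "targets_lnc_db2.tsv")))
  if (file.exists(file.path(dir, "directions.tsv")))
    bundle$directions <- read_directions(file.path(dir, "directions.tsv"))
  if (file.exists(file.path(dir, "immune_sets.gmt")))
    bundle$gene_sets <- read_gmt(file.path(dir, "immune_sets.gmt"))
  class(bundle) <- "cohort_bundle"
  bundle
}
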