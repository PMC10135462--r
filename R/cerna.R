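# Competing endogenous RNA network construction, hub extraction, and
# direction-consistency pruning.
#
# Construction follows the ceRNA logic in three steps:
#  (1) miRNA->mRNA edges restricted to disease-specific mRNAs with DE calls
#      in the opposite direction to the miRNA ("negative correlation"
#      operationalized as opposite DE direction, since the mRNA and miRNA
#      profiles typically come from non-overlapping cohorts);
#  (2) miRNA->lncRNA edges kept only when present in both prediction
#      databases (consensus);
#  (3) assembly keeps only miRNAs with at least one edge of each kind
#      ("continuous targeting"), so every surviving miRNA completes at least
#      one mRNA-miRNA-lncRNA triplet.
# The constructed polarity is mRNA up / miRNA down / lncRNA up; pruning
# removes lncRNA nodes whose measured direction contradicts it.

#' Construct an interaction table
#'
#' @param mirna_id,target_id parallel id vectors for (miRNA, target) edges.
#' @param target_class `"mRNA"` or `"lncRNA"` (single value or per edge).
#' @param source_db label of the source database.
#' @return data.frame of class `interaction_table` with canonicalized miRNA
#'   ids and duplicate edges removed.
#' @export
interaction_table <- function(mirna_id, target_id, target_class, source_db = "db") {
  mirna_id <- canonicalize_mirna_id(mirna_id)
  target_id <- trimws(as.character(target_id))
  if (any(!nzchar(mirna_id)) || any(!nzchar(target_id)))
    stop_cf("empty ids in interaction table")
  target_class <- rep_len(as.character(target_class), length(mirna_id))
  if (!all(target_class %in% c("mRNA", "lncRNA")))
    stop_cf("target_class must be mRNA or lncRNA")
  out <- data.frame(mirna_id = mirna_id, target_id = target_id,
                    target_class = target_class,
                    source_db = rep_len(as.character(source_db), length(mirna_id)),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("mirna_id", "target_id")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_table", class(out))
  out
}

#' Read/write interaction tables (TSV)
#'
#' Columns: `mirna_id`, `target_id`, `target_class`, `source_db`.
#'
#' @param path TSV path.
#' @return an `interaction_table`.
#' @export
read_interactions <- function(path) {
  df <- read_tsv_df(path)
  need <- c("mirna_id", "target_id", "target_class")
  if (!all(need %in% colnames(df)))
    stop_cf("interaction table %s lacks columns: %s", path,
            paste(setdiff(need, colnames(df)), collapse = ", "))
  interaction_table(df$mirna_id, df$target_id, df$target_class,
                    df$source_db %||% "db")
}

#' @rdname read_interactions
#' @param tab an `interaction_table`.
#' @export
write_interactions <- function(tab, path) write_tsv_df(tab, path)

lookup_direction <- function(ids, de) {
  dir <- de$direction[match(ids, de$feature_id)]
  dir[is.na(dir)] <- "ns"
  dir
}

#' Step 1: filtered miRNA-mRNA pairs
#'
#' Keeps (miRNA, mRNA) edges whose mRNA is disease-specific, where both ends
#' carry a non-`ns` DE call and the calls point in opposite directions. With
#' the default polarity only up-mRNA / down-miRNA pairs survive;
#' `polarity = "both"` also admits the mirrored pairs.
#'
#' @param targets miRNA->mRNA `interaction_table`.
#' @param de_mrna,de_mirna thresholded `de_table`s.
#' @param specific_mrnas disease-specific mRNA ids (module-intersected DE).
#' @param polarity `"up-down-up"` (default) or `"both"`.
#' @return data.frame `mirna_id`, `mrna_id`.
#' @export
build_mrna_mirna_pairs <- function(targets, de_mrna, de_mirna, specific_mrnas,
                                   polarity = c("up-down-up", "both")) {
  polarity <- match.arg(polarity)
  if (nrow(targets) == 0L) {
    warn_cf("empty miRNA->mRNA target table")
    return(data.frame(mirna_id = character(0), mrna_id = character(0)))
  }
  tab <- targets[targets$target_class == "mRNA", , drop = FALSE]
  tab <- tab[tab$target_id %in% specific_mrnas, , drop = FALSE]
  dm <- lookup_direction(tab$target_id, de_mrna)
  di <- lookup_direction(tab$mirna_id, de_mirna)
  opp <- if (polarity == "up-down-up") dm == "up" & di == "down"
         else (dm == "up" & di == "down") | (dm == "down" & di == "up")
  out <- data.frame(mirna_id = tab$mirna_id[opp], mrna_id = tab$target_id[opp],
                    stringsAsFactors = FALSE)
  out[!duplicated(out), , drop = FALSE]
}

#' Step 2: consensus miRNA-lncRNA pairs
#'
#' Pairs must appear in both prediction databases; restricted to the miRNAs
#' surviving step 1.
#'
#' @param db1,db2 miRNA->lncRNA `interaction_table`s.
#' @param mirnas miRNA ids to retain.
#' @return data.frame `mirna_id`, `lncrna_id`.
#' @export
consensus_lncrna_pairs <- function(db1, db2, mirnas) {
  for (tab in list(db1, db2))
    if (!all(tab$target_class == "lncRNA"))
      stop_cf("lncRNA tables must have target_class == 'lncRNA'")
  key1 <- paste(db1$mirna_id, db1$target_id, sep = "\r")
  key2 <- paste(db2$mirna_id, db2$target_id, sep = "\r")
  both <- db1[key1 %in% key2, , drop = FALSE]
  both <- both[both$mirna_id %in% canonicalize_mirna_id(mirnas), , drop = FALSE]
  out <- data.frame(mirna_id = both$mirna_id, lncrna_id = both$target_id,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[!duplicated(out), , drop = FALSE]
}

#' Step 3: assemble the tripartite ceRNA network
#'
#' Only miRNAs with at least one mRNA pair and at least one lncRNA pair are
#' retained (continuous targeting); mRNA/lncRNA nodes left without a partner
#' are dropped. Degrees are the incident edge counts in the assembled network.
#'
#' @param mrna_pairs data.frame `mirna_id`, `mrna_id` from
#'   [build_mrna_mirna_pairs()].
#' @param lncrna_pairs data.frame `mirna_id`, `lncrna_id` from
#'   [consensus_lncrna_pairs()].
#' @return object of class `cerna_network`: `nodes` (data.frame `id`, `class`),
#'   `edges` (data.frame `mirna_id`, `partner_id`, `partner_class`), `degree`
#'   (named integer vector).
#' @export
assemble_network <- function(mrna_pairs, lncrna_pairs) {
  mrna_pairs <- mrna_pairs[!duplicated(mrna_pairs), , drop = FALSE]
  lncrna_pairs <- lncrna_pairs[!duplicated(lncrna_pairs), , drop = FALSE]
  keep_mirnas <- intersect(mrna_pairs$mirna_id, lncrna_pairs$mirna_id)
  if (length(keep_mirnas) == 0L)
    warn_cf("no continuous triplets: no miRNA targets both an mRNA and a lncRNA")
  mp <- mrna_pairs[mrna_pairs$mirna_id %in% keep_mirnas, , drop = FALSE]
  lp <- lncrna_pairs[lncrna_pairs$mirna_id %in% keep_mirnas, , drop = FALSE]
  edges <- rbind(
    data.frame(mirna_id = mp$mirna_id, partner_id = mp$mrna_id,
               partner_class = rep("mRNA", nrow(mp)), stringsAsFactors = FALSE),
    data.frame(mirna_id = lp$mirna_id, partner_id = lp$lncrna_id,
               partner_class = rep("lncRNA", nrow(lp)), stringsAsFactors = FALSE))
  edges <- edges[order(edges$partner_class, edges$mirna_id, edges$partner_id), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  ids_m <- unique(mp$mrna_id); ids_l <- unique(lp$lncrna_id)
  nodes <- rbind(
    data.frame(id = ids_m, class = rep("mRNA", length(ids_m)),
               stringsAsFactors = FALSE),
    data.frame(id = keep_mirnas, class = rep("miRNA", length(keep_mirnas)),
               stringsAsFactors = FALSE),
    data.frame(id = ids_l, class = rep("lncRNA", length(ids_l)),
               stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$class, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  deg <- table(factor(c(edges$mirna_id, edges$partner_id), levels = nodes$id))
  degree <- setNames(as.integer(deg), names(deg))
  structure(list(nodes = nodes, edges = edges, degree = degree),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  tab <- table(x$nodes$class)
  cat(sprintf("ceRNA network: %s nodes, %d edges\n",
              paste(sprintf("%d %s", tab, names(tab)), collapse = " + "),
              nrow(x$edges)))
  invisible(x)
}

#' Enumerate mRNA-miRNA-lncRNA triplets
#'
#' All (mRNA, miRNA, lncRNA) combinations for which the network contains both
#' the miRNA-mRNA and the miRNA-lncRNA edge, sorted lexicographically.
#'
#' @param net a `cerna_network`.
#' @return data.frame `mrna_id`, `mirna_id`, `lncrna_id`.
#' @export
enumerate_triplets <- function(net) {
  me <- net$edges[net$edges$partner_class == "mRNA", , drop = FALSE]
  le <- net$edges[net$edges$partner_class == "lncRNA", , drop = FALSE]
  out <- merge(data.frame(mirna_id = me$mirna_id, mrna_id = me$partner_id,
                          stringsAsFactors = FALSE),
               data.frame(mirna_id = le$mirna_id, lncrna_id = le$partner_id,
                          stringsAsFactors = FALSE),
               by = "mirna_id")
  out <- out[, c("mrna_id", "mirna_id", "lncrna_id")]
  out <- out[order(out$mrna_id, out$mirna_id, out$lncrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the top-k hub nodes by degree
#'
#' Nodes are ranked by degree descending, ties broken by id ascending; the
#' subnetwork induced on the top `k` nodes (edges with both endpoints in the
#' hub set) is attached.
#'
#' @param net a `cerna_network`.
#' @param k number of hubs (default 15).
#' @return object of class `hub_set`: `ranking` (data.frame `id`, `class`,
#'   `degree`), `network` (induced `cerna_network`).
#' @export
rank_hubs <- function(net, k = 15) {
  if (nrow(net$nodes) == 0L) stop_cf("empty network")
  k <- check_count(k, "k")
  if (k > nrow(net$nodes)) {
    warn_cf("k = %d exceeds node count %d; returning all nodes", k, nrow(net$nodes))
    k <- nrow(net$nodes)
  }
  deg <- net$degree[net$nodes$id]
  ord <- order(-deg, net$nodes$id)
  top <- net$nodes[ord[seq_len(k)], , drop = FALSE]
  ranking <- data.frame(id = top$id, class = top$class,
                        degree = unname(deg[ord[seq_len(k)]]),
                        stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  sub <- induce_subnetwork(net, ranking$id)
  structure(list(ranking = ranking, network = sub), class = "hub_set")
}

induce_subnetwork <- function(net, ids) {
  edges <- net$edges[net$edges$mirna_id %in% ids & net$edges$partner_id %in% ids, ,
                     drop = FALSE]
  nodes <- net$nodes[net$nodes$id %in% ids, , drop = FALSE]
  rownames(edges) <- rownames(nodes) <- NULL
  deg <- table(factor(c(edges$mirna_id, edges$partner_id), levels = nodes$id))
  structure(list(nodes = nodes, edges = edges,
                 degree = setNames(as.integer(deg), names(deg))),
            class = "cerna_network")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("Hub set: top %d nodes by degree\n", nrow(x$ranking)))
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Prune the hub network by validated directions
#'
#' Under the constructed polarity (mRNA up, miRNA down) a lncRNA belongs in
#' the network only if its measured direction is `"up"`. LncRNAs labelled
#' `"down"` or `"ns"` are removed together with their incident edges; the
#' continuous-targeting rule is then re-applied, so miRNAs left without a
#' lncRNA partner (and any node thereby orphaned) drop out as well, and
#' triplets are re-enumerated on the pruned subnetwork.
#'
#' @param hubs a `hub_set` (or a bare `cerna_network`).
#' @param directions a direction table: data.frame `node_id`, `direction` in
#'   `up`/`down`/`ns`. Every lncRNA in the network must be present.
#' @return list with `hubs` (pruned `hub_set`), `triplets` (re-enumerated),
#'   `removed_lncrnas`.
#' @export
prune_by_validation <- function(hubs, directions) {
  net <- if (inherits(hubs, "hub_set")) hubs$network else hubs
  if (anyDuplicated(directions$node_id)) stop_cf("duplicate ids in direction table")
  lnc <- net$nodes$id[net$nodes$class == "lncRNA"]
  dirs <- directions$direction[match(lnc, directions$node_id)]
  if (anyNA(dirs))
    stop_cf("missing validated direction for lncRNA(s): %s",
            paste(lnc[is.na(dirs)], collapse = ", "))
  drop_lnc <- lnc[dirs != "up"]
  keep_ids <- setdiff(net$nodes$id, drop_lnc)
  sub <- induce_subnetwork(net, keep_ids)
  # re-apply continuous targeting on the surviving edges
  me <- sub$edges[sub$edges$partner_class == "mRNA", , drop = FALSE]
  le <- sub$edges[sub$edges$partner_class == "lncRNA", , drop = FALSE]
  sub <- suppressWarnings(assemble_network(
    data.frame(mirna_id = me$mirna_id, mrna_id = me$partner_id,
               stringsAsFactors = FALSE),
    data.frame(mirna_id = le$mirna_id, lncrna_id = le$partner_id,
               stringsAsFactors = FALSE)))
  deg <- setNames(as.integer(sub$degree), sub$nodes$id)
  ord <- order(-deg, sub$nodes$id)
  pruned <- structure(list(ranking = data.frame(
                             id = sub$nodes$id[ord],
                             class = sub$nodes$class[ord],
                             degree = unname(deg[ord]),
                             stringsAsFactors = FALSE),
                           network = sub),
                      class = "hub_set")
  list(hubs = pruned, triplets = enumerate_triplets(sub),
       removed_lncrnas = drop_lnc)
}

#' Export a ceRNA network
#'
#' Writes an edge-list TSV (`node_a`, `node_b`, `class_a`, `class_b`) and,
#' optionally, GraphML via igraph.
#'
#' @param net a `cerna_network`.
#' @param path output TSV path.
#' @param graphml_path optional GraphML output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, graphml_path = NULL) {
  cls <- setNames(net$nodes$class, net$nodes$id)
  df <- data.frame(node_a = net$edges$mirna_id, node_b = net$edges$partner_id,
                   class_a = "miRNA", class_b = net$edges$partner_class,
                   stringsAsFactors = FALSE)
  write_tsv_df(df, path)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("mirna_id", "partner_id")], directed = FALSE,
      vertices = data.frame(name = net$nodes$id, class = net$nodes$class))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}

#' Read/write a direction table (TSV: node_id, direction)
#'
#' @param path TSV path.
#' @return data.frame `node_id`, `direction`.
#' @export
read_directions <- function(path) {
  df <- read_tsv_df(path)
  if (!all(c("node_id", "direction") %in% colnames(df)))
    stop_cf("direction table %s needs columns node_id, direction", path)
  if (!all(df$direction %in% c("up", "down", "ns")))
    stop_cf("directions must be up/down/ns")
  df
}

#' @rdname read_directions
#' @param directions data.frame `node_id`, `direction`.
#' @export
write_directions <- function(directions, path) write_tsv_df(directions, path)
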