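# Duplication-loss reconciliation of gene trees against a rooted species
# tree, and minimal-DL rooting of unrooted gene trees by exhaustive search
# over root edges.

# Precompute parent pointers, node depths and tip lookup for a species tree.
# Depths count edges from the root; a polytomy contributes one edge, which
# keeps loss counting conservative on soft polytomies.
.species_index <- function(stree) {
  n <- ape::Ntip(stree)
  nn <- n + stree$Nnode
  parent <- integer(nn)
  parent[stree$edge[, 2L]] <- stree$edge[, 1L]
  depth <- integer(nn)
  cw <- ape::reorder.phylo(stree, "cladewise")
  for (i in seq_len(nrow(cw$edge)))
    depth[cw$edge[i, 2L]] <- depth[cw$edge[i, 1L]] + 1L
  list(parent = parent, depth = depth,
       tip_id = stats::setNames(seq_len(n), stree$tip.label),
       root = n + 1L)
}

# LCA of two species-tree nodes via the depth/parent arrays.
.lca2 <- function(a, b, idx) {
  da <- idx$depth[a]; db <- idx$depth[b]
  while (da > db) { a <- idx$parent[a]; da <- da - 1L }
  while (db > da) { b <- idx$parent[b]; db <- db - 1L }
  while (a != b) { a <- idx$parent[a]; b <- idx$parent[b] }
  a
}

.children_list <- function(phy) {
  nn <- ape::Ntip(phy) + phy$Nnode
  ch <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    ch[[p]] <- c(ch[[p]], phy$edge[i, 2L])
  }
  ch
}

#' Deterministically resolve gene-tree polytomies
#'
#' DL counting is defined on binary gene trees. Multifurcations are resolved
#' into an arbitrary but reproducible binary refinement: children are first
#' rotated into sorted-leaf order, then split left-to-right with zero-length
#' edges. The result carries attribute `"resolved_polytomies" = TRUE`.
#'
#' @param gt A rooted `gene_tree`.
#' @return A binary `gene_tree`.
#' @export
resolve_polytomies <- function(gt) {
  stopifnot(inherits(gt, "gene_tree"))
  phy <- gt$phy
  deg <- tabulate(phy$edge[, 1L], ape::Ntip(phy) + phy$Nnode)
  if (all(deg[deg > 0L] <= 2L)) return(gt)
  phy <- ape::rotateConstr(phy, sort(phy$tip.label))
  phy <- ape::multi2di(phy, random = FALSE)
  out <- gene_tree(phy, sep = gt$sep, family_name = gt$family_name,
                   rooted = TRUE)
  attr(out, "resolved_polytomies") <- TRUE
  out
}

#' LCA mapping of a rooted gene tree onto the species tree
#'
#' Maps every gene-tree node to the last common ancestor (in the species
#' tree) of the species carried by its descendant leaves: leaves map to their
#' species' tip, and each internal node maps to the species-tree LCA of its
#' children's images. Non-binary internal nodes are resolved first (see
#' [resolve_polytomies()]), with a warning.
#'
#' @param gtree A rooted `gene_tree` whose leaf species all occur in
#'   `stree` (prune first with [prune_to_species()] otherwise).
#' @param stree The rooted species tree (`phylo`).
#' @return An object of class `reconciliation` with the mapping filled and
#'   event/count fields empty; complete it with [label_events_and_count()].
#' @seealso [reconcile()] for the one-call combination.
#' @export
lca_map <- function(gtree, stree) {
  stopifnot(inherits(gtree, "gene_tree"))
  if (!gtree$rooted)
    stop("gene tree is unrooted; root it first with root_gene_tree()")
  if (gtree$phy$Nnode < ape::Ntip(gtree$phy) - 1L) {
    warning("gene tree '", gtree$family_name,
            "' contains polytomies; resolving deterministically")
  }
  gtree <- resolve_polytomies(gtree)
  phy <- gtree$phy
  n <- ape::Ntip(phy)
  idx <- .species_index(stree)
  sp <- parse_leaf_label(phy$tip.label, gtree$sep)$species_id
  unknown <- setdiff(sp, stree$tip.label)
  if (length(unknown))
    stop("gene-tree species not found in the species tree (prune at ingest): ",
         paste(unknown, collapse = ", "))
  map <- integer(n + phy$Nnode)
  map[seq_len(n)] <- idx$tip_id[sp]
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; v <- po$edge[i, 2L]
    map[p] <- if (map[p] == 0L) map[v] else .lca2(map[p], map[v], idx)
  }
  structure(list(gtree = gtree, stree = stree, idx = idx, map = map,
                 events = NULL, dup_count = NA_integer_,
                 loss_count = NA_integer_, cost = NA_real_, weights = NULL),
            class = "reconciliation")
}

#' Label duplication/speciation events and count duplications and losses
#'
#' An internal gene-tree node is a duplication iff it maps to the same
#' species-tree node as at least one of its children; otherwise it is a
#' speciation. Losses are counted per gene-tree edge (u -> v): with d the
#' number of species-tree edges on the path from M(u) down to M(v), the edge
#' carries d - 1 losses if u is a speciation and d losses if u is a
#' duplication. The total cost is `w_dup * dup_count + w_loss * loss_count`.
#'
#' @param rec A `reconciliation` from [lca_map()].
#' @param weights Named numeric vector `c(dup = , loss = )`; unit costs by
#'   default (the weighting used by conventional DL rooting is not uniquely
#'   standardized, so it is configurable).
#' @return The completed `reconciliation`, with `events` (character vector
#'   over gene-tree nodes), `dup_count`, `loss_count`, `cost` and a per-edge
#'   loss vector `edge_losses` aligned with `gtree$phy$edge` rows.
#' @export
label_events_and_count <- function(rec, weights = c(dup = 1, loss = 1)) {
  stopifnot(inherits(rec, "reconciliation"))
  stopifnot(all(c("dup", "loss") %in% names(weights)), all(weights >= 0))
  phy <- rec$gtree$phy
  n <- ape::Ntip(phy)
  nn <- n + phy$Nnode
  ch <- .children_list(phy)
  events <- rep(NA_character_, nn)
  for (v in (n + 1L):nn)
    events[v] <- if (any(rec$map[ch[[v]]] == rec$map[v]))
      "duplication" else "speciation"
  dup_count <- sum(events == "duplication", na.rm = TRUE)
  e <- phy$edge
  d <- rec$idx$depth[rec$map[e[, 2L]]] - rec$idx$depth[rec$map[e[, 1L]]]
  edge_losses <- d - as.integer(events[e[, 1L]] == "speciation")
  loss_count <- sum(edge_losses)
  rec$events <- events
  rec$dup_count <- as.integer(dup_count)
  rec$loss_count <- as.integer(loss_count)
  rec$edge_losses <- edge_losses
  rec$weights <- weights
  rec$cost <- unname(weights["dup"] * dup_count + weights["loss"] * loss_count)
  rec
}

#' Reconcile a rooted gene tree against the species tree
#'
#' Convenience wrapper: [lca_map()] followed by [label_events_and_count()].
#'
#' @inheritParams lca_map
#' @inheritParams label_events_and_count
#' @return A completed `reconciliation`.
#' @examples
#' st <- species_tree(read_newick("((A,B),(C,D));"))
#' gt <- read_gene_tree("(A|a,(C|c,D|d));", rootedness_hint = "rooted")
#' rec <- reconcile(gt, st)
#' c(rec$dup_count, rec$loss_count) # 0 duplications, 1 loss (the B copy)
#' @export
reconcile <- function(gtree, stree, weights = c(dup = 1, loss = 1)) {
  label_events_and_count(lca_map(gtree, stree), weights)
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("DL reconciliation of '%s': %s duplication(s), %s loss(es), cost %s\n",
              x$gtree$family_name, x$dup_count, x$loss_count,
              format(x$cost)))
  invisible(x)
}

#' Unroot a gene tree
#'
#' @param gt A rooted `gene_tree`.
#' @return The unrooted `gene_tree` (basal multifurcation of degree >= 3).
#' @export
unroot_gene_tree <- function(gt) {
  stopifnot(inherits(gt, "gene_tree"))
  if (!gt$rooted) return(gt)
  gene_tree(ape::unroot(gt$phy), sep = gt$sep,
            family_name = gt$family_name, rooted = FALSE)
}

.tips_under <- function(phy, node) {
  n <- ape::Ntip(phy)
  if (node <= n) return(phy$tip.label[node])
  ape::extract.clade(phy, node)$tip.label
}

# Re-root an unrooted gene tree on the edge indexed by row i of phy$edge.
.root_at_edge <- function(gt, i) {
  phy <- gt$phy
  og <- .tips_under(phy, phy$edge[i, 2L])
  rphy <- ape::root(phy, outgroup = og, resolve.root = TRUE)
  gene_tree(rphy, sep = gt$sep, family_name = gt$family_name, rooted = TRUE)
}

# Sorted leaf labels of the smaller child clade of the root, pasted into a
# single comparison key. Used only to break exact cost-and-rank ties.
.smaller_side_key <- function(gt) {
  phy <- gt$phy
  root <- ape::Ntip(phy) + 1L
  kids <- phy$edge[phy$edge[, 1L] == root, 2L]
  sides <- lapply(kids, function(k) sort(.tips_under(phy, k)))
  len <- lengths(sides)
  keys <- vapply(sides, paste, character(1L), collapse = ",")
  cand <- which(len == min(len))
  min(keys[cand])
}

#' Species-tree-guided rooting of an unrooted gene tree
#'
#' Exhaustive minimal duplication-loss rooting: every edge of the unrooted
#' gene tree is tried as the root edge, the rooted tree is reconciled against
#' the species tree, and the root minimizing the weighted DL cost is chosen.
#' The full edge-by-edge cost table and the tie set (edges sharing the
#' minimal cost) are returned so rooting ambiguity can be audited.
#'
#' Ties are broken deterministically: among minimal-cost edges, prefer the
#' rooting whose root node maps closest to the species-tree root (smallest
#' depth of M(root)); remaining ties go to the lexicographically smallest
#' sorted leaf set of the smaller root-child clade.
#'
#' @param gtree An unrooted `gene_tree` with >= 3 leaves (a rooted input is
#'   unrooted first).
#' @param stree The rooted species tree.
#' @param weights Event weights as in [label_events_and_count()].
#' @return An object of class `rooting_result`: list with `edge_table`
#'   (data frame edge/parent/child/dup/loss/cost), `best_edge`, `tie_set`,
#'   `cost`, `rooted_tree` (a rooted `gene_tree`) and `reconciliation`.
#' @export
root_gene_tree <- function(gtree, stree, weights = c(dup = 1, loss = 1)) {
  stopifnot(inherits(gtree, "gene_tree"))
  if (ape::Ntip(gtree$phy) < 3L)
    stop("need at least 3 leaves to root a gene tree")
  gtree <- unroot_gene_tree(gtree)
  phy <- gtree$phy
  ne <- nrow(phy$edge)
  recs <- vector("list", ne)
  rooted <- vector("list", ne)
  for (i in seq_len(ne)) {
    rooted[[i]] <- .root_at_edge(gtree, i)
    recs[[i]] <- label_events_and_count(lca_map(rooted[[i]], stree), weights)
  }
  costs <- vapply(recs, function(r) r$cost, numeric(1L))
  tie_set <- which(costs == min(costs))
  best <- tie_set[1L]
  if (length(tie_set) > 1L) {
    rank_ <- vapply(tie_set, function(i) {
      r <- recs[[i]]
      r$idx$depth[r$map[ape::Ntip(r$gtree$phy) + 1L]]
    }, integer(1L))
    cand <- tie_set[rank_ == min(rank_)]
    if (length(cand) > 1L) {
      keys <- vapply(cand, function(i) .smaller_side_key(rooted[[i]]),
                     character(1L))
      cand <- cand[order(keys)]
    }
    best <- cand[1L]
  }
  edge_table <- data.frame(
    edge = seq_len(ne),
    parent = phy$edge[, 1L],
    child = phy$edge[, 2L],
    dup = vapply(recs, function(r) r$dup_count, integer(1L)),
    loss = vapply(recs, function(r) r$loss_count, integer(1L)),
    cost = costs)
  structure(list(edge_table = edge_table, best_edge = best,
                 tie_set = tie_set, cost = costs[best],
                 rooted_tree = rooted[[best]], reconciliation = recs[[best]]),
            class = "rooting_result")
}

#' @export
print.rooting_result <- function(x, ...) {
  cat(sprintf(
    "Minimal-DL rooting: cost %s at edge %d of %d (%d tie(s); dup %d, loss %d)\n",
    format(x$cost), x$best_edge, nrow(x$edge_table), length(x$tie_set),
    x$reconciliation$dup_count, x$reconciliation$loss_count))
  invisible(x)
}

#' Species bipartition induced by the root of a rooted gene tree
#'
#' Returns the two sets of species labels descending from the root's two
#' children, e.g. to compare a recovered root against the species-tree root
#' split.
#'
#' @param gt A rooted `gene_tree` (or a plain rooted `phylo`, in which case
#'   tip labels are used verbatim).
#' @return A list of two sorted character vectors of species ids.
#' @export
root_bipartition <- function(gt) {
  if (inherits(gt, "gene_tree")) {
    phy <- gt$phy
    lab2sp <- stats::setNames(gt$leaves$species_id, gt$leaves$label)
  } else {
    phy <- gt
    lab2sp <- stats::setNames(phy$tip.label, phy$tip.label)
  }
  root <- ape::Ntip(phy) + 1L
  kids <- phy$edge[phy$edge[, 1L] == root, 2L]
  if (length(kids) != 2L) stop("tree root is not binary")
  lapply(kids, function(k) sort(unique(unname(lab2sp[.tips_under(phy, k)]))))
}
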