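# Independent brute-force duplication-loss reconciliation oracle.
# Deliberately naive: ancestor lists, pairwise LCA by list intersection,
# losses by explicit node-by-node path walking. Shares no computation with
# the package implementation beyond ape's tree containers.

oracle_parent <- function(phy) {
  parent <- integer(ape::Ntip(phy) + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  parent
}

# Ancestor list of a node, from the node itself up to the root.
oracle_ancestors <- function(node, parent, root) {
  out <- node
  while (node != root) {
    node <- parent[node]
    out <- c(out, node)
  }
  out
}

oracle_lca <- function(a, b, parent, root) {
  anc_a <- oracle_ancestors(a, parent, root)
  anc_b <- oracle_ancestors(b, parent, root)
  anc_a[match(TRUE, anc_a %in% anc_b)]
}

oracle_tips_under <- function(phy, node) {
  n <- ape::Ntip(phy)
  if (node <= n) return(node)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, oracle_tips_under, phy = phy))
}

# DL reconciliation of a rooted binary gene tree (tips labelled
# "species|gene") against a rooted species tree: mapping by reducing the
# pairwise LCA over *all* descendant tip species of each node, duplication
# if a node shares its image with a child, losses by walking the
# species-tree path between parent and child images.
oracle_reconcile <- function(rphy, stree, wd = 1, wl = 1, sep = "|") {
  sp_parent <- oracle_parent(stree)
  sp_root <- ape::Ntip(stree) + 1
  sp_of <- function(lab) sub(paste0("\\", sep, ".*$"), "", lab)
  n <- ape::Ntip(rphy)
  nn <- n + rphy$Nnode
  g_parent <- oracle_parent(rphy)
  map <- integer(nn)
  for (v in seq_len(nn)) {
    tips <- oracle_tips_under(rphy, v)
    sps <- match(sp_of(rphy$tip.label[tips]), stree$tip.label)
    m <- sps[1]
    for (s in sps[-1]) m <- oracle_lca(m, s, sp_parent, sp_root)
    map[v] <- m
  }
  event <- rep(NA_character_, nn)
  for (v in (n + 1):nn) {
    kids <- rphy$edge[rphy$edge[, 1] == v, 2]
    event[v] <- if (any(map[kids] == map[v])) "duplication" else "speciation"
  }
  losses <- 0L
  for (i in seq_len(nrow(rphy$edge))) {
    u <- rphy$edge[i, 1]; v <- rphy$edge[i, 2]
    d <- 0L
    node <- map[v]
    while (node != map[u]) {
      node <- sp_parent[node]
      d <- d + 1L
    }
    losses <- losses + if (event[u] == "speciation") d - 1L else d
  }
  dups <- sum(event == "duplication", na.rm = TRUE)
  list(map = map, event = event, dup = dups, loss = losses,
       cost = wd * dups + wl * losses)
}

# Exhaustive rooting oracle: cost of rooting the unrooted gene tree on each
# of its edges, in phy$edge row order.
oracle_root_costs <- function(uphy, stree, wd = 1, wl = 1, sep = "|") {
  vapply(seq_len(nrow(uphy$edge)), function(i) {
    child <- uphy$edge[i, 2]
    og <- uphy$tip.label[oracle_tips_under(uphy, child)]
    rphy <- ape::root(uphy, outgroup = og, resolve.root = TRUE)
    oracle_reconcile(rphy, stree, wd, wl, sep)$cost
  }, numeric(1))
}
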