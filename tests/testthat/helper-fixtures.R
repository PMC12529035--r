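# Shared fixtures and small structural utilities for the tests.

# Canonical topology string of a rooted tree: children sorted recursively,
# so two trees are topologically identical iff their strings match.
# `relabel` maps tip labels (e.g. gene leaf -> species) before comparison.
canonical_topology <- function(phy, relabel = identity) {
  n <- ape::Ntip(phy)
  recurse <- function(node) {
    if (node <= n) return(relabel(phy$tip.label[node]))
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    paste0("(", paste(sort(vapply(kids, recurse, character(1))),
                      collapse = ","), ")")
  }
  recurse(n + 1)
}

# Is a simulated family one-copy-per-species and congruent with the species
# tree (i.e. identical rooted topology after mapping leaves to species)?
is_one_copy_congruent <- function(gt, stree) {
  sp <- gt$leaves$species_id
  if (length(sp) != ape::Ntip(stree)) return(FALSE)
  if (anyDuplicated(sp) || !setequal(sp, stree$tip.label)) return(FALSE)
  to_sp <- function(lab) sub("\\|.*$", "", lab)
  identical(canonical_topology(gt$phy, to_sp), canonical_topology(stree))
}

# Same, relative to the complete species clade under the gene root's image:
# the DL loss count sums over gene-tree edges, so species clades lying
# entirely outside the MRCA of the represented species contribute no cost,
# while any species missing *inside* that clade is charged as a loss. Zero
# cost therefore characterizes one copy per species of the full clade under
# MRCA(represented species), with congruent topology.
is_one_copy_congruent_induced <- function(gt, stree) {
  sp <- gt$leaves$species_id
  if (anyDuplicated(sp)) return(FALSE)
  if (length(sp) < 2) return(FALSE)
  mrca <- ape::getMRCA(stree, sp)
  sub <- if (mrca == ape::Ntip(stree) + 1) stree
         else ape::extract.clade(stree, mrca)
  if (!setequal(sp, sub$tip.label)) return(FALSE)
  to_sp <- function(lab) sub("\\|.*$", "", lab)
  identical(canonical_topology(gt$phy, to_sp), canonical_topology(sub))
}

quartet_species <- function() species_tree(read_newick("((A,B),(C,D));"))

# Two disjoint cherries (2-tip clades) of a species tree, as tip-label pairs;
# used to place trait-linked forced losses on internal branches.
disjoint_cherries <- function(stree, k = 2) {
  n <- ape::Ntip(stree)
  internal <- unique(stree$edge[, 1])
  cherries <- Filter(function(nd) {
    kids <- stree$edge[stree$edge[, 1] == nd, 2]
    length(kids) == 2 && all(kids <= n)
  }, internal)
  if (length(cherries) < k) stop("species tree has fewer than ", k, " cherries")
  lapply(cherries[seq_len(k)], function(nd)
    stree$tip.label[stree$edge[stree$edge[, 1] == nd, 2]])
}
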