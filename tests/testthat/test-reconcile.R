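test_that("LCA mapping follows hand-computed images", {
  st <- quartet_species()
  gt <- read_gene_tree("(A|a,(C|c,D|d));", rootedness_hint = "rooted")
  rec <- lca_map(gt, st)
  phy <- rec$gtree$phy
  n <- ape::Ntip(phy)
  sroot <- ape::Ntip(st) + 1
  cd <- ape::getMRCA(st, c("C", "D"))
  expect_equal(rec$map[n + 1], sroot)                       # gene root -> S root
  expect_equal(rec$map[ape::getMRCA(phy, c("C|c", "D|d"))], cd)
  # a within-species cherry maps to that species' tip
  gt2 <- read_gene_tree("((A|a1,A|a2),C|c);", rootedness_hint = "rooted")
  rec2 <- lca_map(gt2, st)
  expect_equal(rec2$map[ape::getMRCA(rec2$gtree$phy, c("A|a1", "A|a2"))],
               match("A", st$tip.label))
  # unmapped species is an error at this stage
  gt3 <- read_gene_tree("(Zz|z,(C|c,D|d));", rootedness_hint = "rooted")
  expect_error(lca_map(gt3, st), "prune")
})

test_that("event labelling and DL counts match hand counts and weights", {
  st <- quartet_species()
  # congruent one-copy family: zero everything
  gt0 <- read_gene_tree("((A|a,B|b),(C|c,D|d));", rootedness_hint = "rooted")
  rec0 <- reconcile(gt0, st)
  expect_equal(c(rec0$dup_count, rec0$loss_count, rec0$cost), c(0, 0, 0))
  expect_true(all(rec0$events[!is.na(rec0$events)] == "speciation"))
  # missing B: one loss on the root->A edge
  rec1 <- reconcile(read_gene_tree("(A|a,(C|c,D|d));",
                                   rootedness_hint = "rooted"), st)
  expect_equal(c(rec1$dup_count, rec1$loss_count, rec1$cost), c(0, 1, 1))
  # root duplication on a two-species quartet
  st2 <- species_tree(read_newick("(A,B);"))
  rec2 <- reconcile(read_gene_tree("((A|a1,B|b1),(A|a2,B|b2));",
                                   rootedness_hint = "rooted"), st2)
  expect_equal(c(rec2$dup_count, rec2$loss_count, rec2$cost), c(1, 0, 1))
  # non-unit weights scale the cost
  rec3 <- reconcile(read_gene_tree("(A|a,(C|c,D|d));",
                                   rootedness_hint = "rooted"), st,
                    weights = c(dup = 2, loss = 3))
  expect_equal(rec3$cost, 3)
})

test_that("counts are invariant under child-order permutations of both trees", {
  st_a <- species_tree(read_newick("((A,B),(C,D));"))
  st_b <- species_tree(read_newick("((D,C),(B,A));"))
  forms <- c("((A|a1,A|a2),(C|c,D|d));",
             "((D|d,C|c),(A|a2,A|a1));")
  recs <- lapply(forms, function(nwk) lapply(list(st_a, st_b), function(st)
    reconcile(read_gene_tree(nwk, rootedness_hint = "rooted"), st)))
  counts <- lapply(unlist(recs, recursive = FALSE),
                   function(r) c(r$dup_count, r$loss_count))
  for (ct in counts[-1]) expect_identical(ct, counts[[1]])
})

test_that("rooting recovers hand-enumerable optima, cost tables, and ties", {
  st <- quartet_species()
  # congruent quartet: unique zero-cost root on the central edge
  rr <- root_gene_tree(read_gene_tree("(A|a,B|b,(C|c,D|d));"), st)
  expect_equal(nrow(rr$edge_table), 5)
  expect_equal(rr$cost, 0)
  expect_length(rr$tie_set, 1)
  expect_equal(sort(vapply(root_bipartition(rr$rooted_tree), paste,
                           character(1), collapse = ",")),
               c("A,B", "C,D"))
  # duplicated two-species quartet: minimum 1 on the internal edge only
  st2 <- species_tree(read_newick("(A,B);"))
  gq <- read_gene_tree("((A|a1,B|b1),(A|a2,B|b2));")
  rrq <- root_gene_tree(gq, st2)
  expect_equal(rrq$cost, 1)
  internal <- with(rrq$edge_table, child > ape::Ntip(gq$phy))
  expect_equal(rrq$edge_table$cost[internal], 1)
  expect_true(all(rrq$edge_table$cost[!internal] > 1))
  # 3-leaf star: rooting on the C pendant edge is free
  st3 <- species_tree(read_newick("((A,B),C);"))
  g3 <- read_gene_tree("(A|a,B|b,C|c);")
  rr3 <- root_gene_tree(g3, st3)
  expect_equal(rr3$cost, 0)
  best_child <- rr3$edge_table$child[rr3$best_edge]
  expect_equal(g3$phy$tip.label[best_child], "C|c")
  expect_error(root_gene_tree(read_gene_tree("(A|a,B|b);"), st),
               "3 leaves")
})

test_that("rooting cost table equals the brute-force oracle on random families", {
  sp <- simulate_species_tree(10, 1, 81)
  sc <- sim_scenario(sp, 0.15, 0.15, n_families = 60, seed = 19)
  checked <- 0
  for (i in 1:60) {
    tr <- simulate_gene_family(sc, i)
    if (is.null(tr$gene_tree)) next
    nl <- nrow(tr$gene_tree$leaves)
    if (nl < 3 || nl > 10) next
    ug <- unroot_gene_tree(tr$gene_tree)
    rr <- root_gene_tree(ug, sp)
    oc <- oracle_root_costs(ug$phy, sp)
    expect_equal(rr$edge_table$cost, oc, label = tr$family_name)
    expect_equal(rr$cost, min(oc))
    expect_setequal(rr$tie_set, which(oc == min(oc)))
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("cost is zero exactly for one-copy families congruent with their induced species subtree", {
  # losses are summed over gene-tree edges, so species-tree clades with no
  # surviving copy contribute no cost: zero cost characterizes one copy per
  # represented species plus congruence with the induced species subtree
  sp <- simulate_species_tree(8, 1, 91)
  sc_mix <- sim_scenario(sp, 0.15, 0.15, n_families = 30, seed = 29)
  sc_null <- sim_scenario(sp, 0, 0, n_families = 10, seed = 29)
  fams <- c(lapply(1:30, function(i) simulate_gene_family(sc_mix, i)),
            lapply(1:10, function(i) simulate_gene_family(sc_null, i)))
  zero_seen <- FALSE; nonzero_seen <- FALSE
  for (tr in fams) {
    if (is.null(tr$gene_tree)) next
    rec <- reconcile(tr$gene_tree, sp)
    congruent <- is_one_copy_congruent_induced(tr$gene_tree, sp)
    expect_identical(rec$cost == 0, congruent, label = tr$family_name)
    # full-coverage congruence implies induced congruence, never the reverse
    if (is_one_copy_congruent(tr$gene_tree, sp))
      expect_true(congruent)
    if (congruent) zero_seen <- TRUE else nonzero_seen <- TRUE
  }
  expect_true(zero_seen)
  expect_true(nonzero_seen)
})

test_that("polytomous gene trees are resolved deterministically before counting", {
  st <- quartet_species()
  gt <- read_gene_tree("(A|a,B|b,C|c,D|d);", rootedness_hint = "rooted")
  expect_warning(rec <- reconcile(gt, st), "polytom")
  expect_true(isTRUE(attr(rec$gtree, "resolved_polytomies")))
  # same multifurcation written in a different child order: same counts
  gt2 <- read_gene_tree("(D|d,C|c,B|b,A|a);", rootedness_hint = "rooted")
  rec2 <- suppressWarnings(reconcile(gt2, st))
  expect_identical(c(rec$dup_count, rec$loss_count),
                   c(rec2$dup_count, rec2$loss_count))
})
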