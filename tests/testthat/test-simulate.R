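test_that("species tree simulation is deterministic, named, and ultrametric", {
  a <- simulate_species_tree(10, 1, 3)
  b <- simulate_species_tree(10, 1, 3)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_setequal(a$tip.label, paste0("S", 1:10))
  depths <- ape::node.depth.edgelength(a)[1:10]
  expect_lt(diff(range(depths)), 1e-9)
  expect_error(simulate_species_tree(1, 1, 1), "n_taxa")
})

test_that("whole datasets regenerate bit-identically from the same seed", {
  sp <- simulate_species_tree(8, 1, 11)
  sc <- sim_scenario(sp, 0.15, 0.15, trait_loss_branches = list("S3"),
                     p_forced_loss = 0.5, frac_trait_linked = 0.5,
                     n_families = 20, completeness = 0.9, seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(sc, d1)
  simulate_dataset(sc, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # per-family regeneration is independent of the rest of the dataset
  out <- simulate_dataset(sc)
  t7 <- simulate_gene_family(sc, 7)
  expect_identical(t7$newick, out$truths[[7]]$newick)
  expect_identical(t7$true_presence, out$truths[[7]]$true_presence)
})

test_that("without events gene trees are congruent one-copy families", {
  sp <- simulate_species_tree(9, 1, 21)
  sc <- sim_scenario(sp, 0, 0, n_families = 3, seed = 9)
  for (i in 1:3) {
    tr <- simulate_gene_family(sc, i)
    expect_true(all(tr$true_presence))
    expect_true(all(tr$copy_number == 1L))
    expect_equal(nrow(tr$events), 0)
    expect_true(is_one_copy_congruent(tr$gene_tree, sp))
  }
})

test_that("copy numbers are monotone along lineages at one-sided rates", {
  sp <- simulate_species_tree(10, 1, 31)
  # pure duplication: every species keeps >= 1 copy
  sc_dup <- sim_scenario(sp, 0.3, 0, n_families = 25, seed = 2)
  for (i in 1:25) {
    tr <- simulate_gene_family(sc_dup, i)
    expect_true(all(tr$copy_number >= 1L))
    expect_false(any(tr$events$event %in% c("loss", "forced_loss")))
  }
  # pure loss: never more than the single entering copy
  sc_loss <- sim_scenario(sp, 0, 0.3, n_families = 25, seed = 2)
  for (i in 1:25) {
    tr <- simulate_gene_family(sc_loss, i)
    expect_true(all(tr$copy_number <= 1L))
    expect_false(any(tr$events$event == "dup"))
  }
})

test_that("forced losses are sound: only on trait branches, only for trait-linked families, Dollo-irreversible", {
  sp <- simulate_species_tree(12, 1, 41)
  cherries <- disjoint_cherries(sp, 2)
  focal <- unlist(cherries)
  sc <- sim_scenario(sp, 0.1, 0.1, trait_loss_branches = cherries,
                     p_forced_loss = 1, frac_trait_linked = 0.5,
                     n_families = 40, seed = 13)
  trait_node_labels <- paste0("node", sc$trait_nodes)
  for (i in 1:40) {
    tr <- simulate_gene_family(sc, i)
    forced <- tr$events[tr$events$event == "forced_loss", ]
    if (!tr$trait_linked) {
      expect_equal(nrow(forced), 0)
    } else {
      expect_true(all(forced$branch %in% trait_node_labels))
      # with p = 1, no descendant of any trait branch retains the family
      expect_true(all(!tr$true_presence[focal]))
      if (!is.null(tr$gene_tree))
        expect_false(any(tr$gene_tree$leaves$species_id %in% focal))
    }
  }
  # a terminal trait branch with p = 1 and no background events
  sc2 <- sim_scenario(sp, 0, 0, trait_loss_branches = list("S3"),
                      p_forced_loss = 1, frac_trait_linked = 1,
                      n_families = 1, seed = 3)
  tr2 <- simulate_gene_family(sc2, 1)
  expect_false(tr2$true_presence[["S3"]])
  expect_true(all(tr2$true_presence[setdiff(sp$tip.label, "S3")]))
})

test_that("true_presence agrees with the surviving gene-tree leaves", {
  sp <- simulate_species_tree(8, 1, 51)
  sc <- sim_scenario(sp, 0.2, 0.2, n_families = 30, seed = 17)
  for (i in 1:30) {
    tr <- simulate_gene_family(sc, i)
    expect_identical(tr$true_presence, tr$copy_number > 0L)
    if (!is.null(tr$gene_tree)) {
      leaf_sp <- tr$gene_tree$leaves$species_id
      expect_setequal(names(which(tr$true_presence)), unique(leaf_sp))
      expect_equal(nrow(tr$gene_tree$leaves), sum(tr$copy_number))
    }
  }
})

test_that("detection dropout behaves as per-cell Bernoulli thinning", {
  sp <- simulate_species_tree(10, 1, 61)
  sc <- sim_scenario(sp, 0, 0, n_families = 100, seed = 23)
  truths <- lapply(1:100, function(i) simulate_gene_family(sc, i))
  # c = 1: observation equals truth; c = 0: everything absent
  m1 <- apply_detection_noise(truths, 1, seed = 1)
  expect_true(all(m1$presence))
  m0 <- apply_detection_noise(truths, 0, seed = 1)
  expect_false(any(m0$presence))
  # c = 0.9 over 1000 true-present cells: observed count within 3 sigma
  m9 <- apply_detection_noise(truths, 0.9, seed = 99)
  k <- sum(m9$presence)
  expect_lt(abs(k - 1000 * 0.9), 3 * sqrt(1000 * 0.9 * 0.1))
  expect_true(all(m9$provenance[m9$presence] == "tree"))
  expect_error(apply_detection_noise(truths, 1.2, seed = 1), "\\[0,1\\]")
})

test_that("scenario validation catches bad rates, probabilities, and branches", {
  sp <- simulate_species_tree(6, 1, 71)
  expect_error(sim_scenario(sp, -0.1, 0.1), "dup_rate")
  expect_error(sim_scenario(sp, 0.1, 0.1, p_forced_loss = 1.5),
               "p_forced_loss")
  expect_error(sim_scenario(sp, 0.1, 0.1,
                            trait_loss_branches = list("Nope")), "Nope")
  expect_error(sim_scenario(sp, 0.1, 0.1,
                            trait_loss_branches = list(sp$tip.label)),
               "root")
  # zero families: empty but valid outputs
  sc0 <- sim_scenario(sp, 0.1, 0.1, n_families = 0, seed = 1)
  d <- withr::local_tempdir()
  out <- simulate_dataset(sc0, d)
  expect_length(out$truths, 0)
  expect_equal(length(readLines(file.path(d, "truth.tsv"))), 1)
  # no trait-linked families => no forced losses anywhere
  sc_none <- sim_scenario(sp, 0.1, 0.1, trait_loss_branches = list("S2"),
                          frac_trait_linked = 0, n_families = 10, seed = 2)
  for (i in 1:10)
    expect_false(any(simulate_gene_family(sc_none, i)$events$event ==
                     "forced_loss"))
})
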