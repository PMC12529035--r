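# Synthetic gene-family generator: duplication-loss birth-death evolution on
# a species tree, trait-linked forced losses on designated branches, and
# per-species detection dropout. Every family carries full ground truth so
# downstream inference (rooting, extraction, occurrence, screening) can be
# validated end to end.

#' Simulate a Yule species tree
#'
#' Pure-birth tree with `n_taxa` leaves named `S1..Sn`, simulated with
#' [ape::rphylo()] (hence ultrametric), deterministic given `seed`.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param birth_rate Speciation rate (> 0), per unit time.
#' @param seed Integer seed.
#' @return A rooted ultrametric `phylo` with attribute `"rooted" = TRUE`.
#' @export
simulate_species_tree <- function(n_taxa, birth_rate = 1, seed = 1) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  set.seed(seed)
  phy <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  phy$tip.label <- paste0("S", seq_len(n_taxa))
  attr(phy, "rooted") <- TRUE
  phy
}

#' Default detection-completeness presets
#'
#' Per-species probabilities that a truly present gene family is recovered,
#' emulating typical assembly completeness: 0.90 for genome assemblies and
#' 0.77 for transcriptome assemblies (rounded Busco completeness means of
#' large plant genome/transcriptome compilations).
#'
#' @param type Character vector over `c("genome", "transcriptome")`.
#' @return Numeric vector of completeness probabilities.
#' @export
default_completeness <- function(type) {
  preset <- c(genome = 0.90, transcriptome = 0.77)
  bad <- setdiff(type, names(preset))
  if (length(bad)) stop("unknown completeness preset: ",
                        paste(bad, collapse = ", "))
  unname(preset[type])
}

.clade_node <- function(stree, tips) {
  tips <- as.character(tips)
  miss <- setdiff(tips, stree$tip.label)
  if (length(miss))
    stop("trait branch tips not in species tree: ", paste(miss, collapse = ", "))
  node <- if (length(tips) == 1L) match(tips, stree$tip.label)
          else ape::getMRCA(stree, tips)
  if (node == ape::Ntip(stree) + 1L)
    stop("a trait branch cannot be the species-tree root (it has no branch)")
  node
}

.completeness_vector <- function(completeness, species) {
  if (length(completeness) == 1L && is.null(names(completeness)))
    completeness <- stats::setNames(rep(completeness, length(species)), species)
  miss <- setdiff(species, names(completeness))
  if (length(miss))
    stop("completeness not defined for species: ", paste(miss, collapse = ", "))
  cs <- completeness[species]
  if (any(cs < 0 | cs > 1)) stop("completeness probabilities must lie in [0,1]")
  cs
}

#' Define a gene-family simulation scenario
#'
#' A scenario fixes the species tree, the per-copy duplication and loss rates
#' of the linear birth-death process, the trait-linked loss mechanism (which
#' species-tree branches carry forced losses, with what probability, and what
#' fraction of families is trait-linked), the number of families, per-species
#' detection completeness, and the master seed.
#'
#' @param species_tree Rooted species tree (`phylo`) with branch lengths.
#' @param dup_rate,loss_rate Per-copy event rates (>= 0) per unit branch
#'   length.
#' @param trait_loss_branches List identifying species-tree branches: each
#'   element is a character vector of tip labels whose MRCA's parent edge is
#'   the trait branch (a single tip label selects its terminal branch).
#' @param p_forced_loss Probability in `[0,1]` that a trait-linked family is
#'   terminated (all copies) on each trait branch it enters.
#' @param frac_trait_linked Fraction of families flagged trait-linked; the
#'   first `round(frac_trait_linked * n_families)` family indices carry the
#'   flag, so each family regenerates independently of the others.
#' @param n_families Number of families (>= 0).
#' @param completeness Scalar or per-species named vector of detection
#'   probabilities in `[0,1]` (see [default_completeness()]).
#' @param seed Integer master seed; per-family streams are derived from it.
#' @param sep Leaf-label separator used for simulated gene trees.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(species_tree, dup_rate = 0.1, loss_rate = 0.1,
                         trait_loss_branches = list(), p_forced_loss = 1,
                         frac_trait_linked = 0, n_families = 100,
                         completeness = 1, seed = 1, sep = "|") {
  species_tree <- species_tree(species_tree)
  if (is.null(species_tree$edge.length))
    stop("the scenario species tree needs branch lengths")
  stopifnot(dup_rate >= 0, loss_rate >= 0,
            p_forced_loss >= 0, p_forced_loss <= 1,
            frac_trait_linked >= 0, frac_trait_linked <= 1,
            n_families >= 0)
  if (!is.list(trait_loss_branches))
    trait_loss_branches <- as.list(trait_loss_branches)
  trait_nodes <- vapply(trait_loss_branches, .clade_node,
                        integer(1L), stree = species_tree)
  cs <- .completeness_vector(completeness, species_tree$tip.label)
  structure(list(species_tree = species_tree, dup_rate = dup_rate,
                 loss_rate = loss_rate,
                 trait_loss_branches = trait_loss_branches,
                 trait_nodes = trait_nodes, p_forced_loss = p_forced_loss,
                 frac_trait_linked = frac_trait_linked,
                 n_families = as.integer(n_families),
                 completeness = cs, seed = as.integer(seed), sep = sep),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulation scenario: %d families on %d species ",
    "(dup %.3g, loss %.3g per unit length; %d trait branch(es), ",
    "p_forced_loss %.3g, %.0f%% trait-linked; seed %d)\n"),
    x$n_families, ape::Ntip(x$species_tree), x$dup_rate, x$loss_rate,
    length(x$trait_nodes), x$p_forced_loss, 100 * x$frac_trait_linked,
    x$seed))
  invisible(x)
}

# Deterministic per-family seed derived from (master seed, family index).
# Double arithmetic stays exact below 2^53; the result fits a 32-bit int.
.family_seed <- function(seed, family_index) {
  as.integer(((seed %% 2147483647) * 48271 + family_index * 16807) %% 2147483647)
}

.is_trait_linked <- function(scenario, family_index) {
  family_index <= round(scenario$frac_trait_linked * scenario$n_families)
}

#' Simulate one gene family under the scenario
#'
#' One gene lineage enters the species-tree root. Along every branch each
#' copy evolves under an independent linear birth-death process: it
#' duplicates at rate `dup_rate` and dies at rate `loss_rate` per unit branch
#' length. If the family is trait-linked then, independently for each trait
#' branch, with probability `p_forced_loss` every copy on that branch is
#' terminated at the branch midpoint (one `forced_loss` event); nothing
#' survives into the subtended clade, encoding Dollo-like irreversibility of
#' the loss. Reproducible given `(scenario$seed, family_index)`.
#'
#' @param scenario A `sim_scenario`.
#' @param family_index Positive integer index of the family.
#' @return An object of class `sim_truth`: list with `family_name`,
#'   `trait_linked`, `true_presence` (named logical; >= 1 surviving copy),
#'   `copy_number` (named integer), `events` (data frame branch / node /
#'   event / time, event in dup/loss/forced_loss), `gene_tree` (a rooted
#'   `gene_tree` of the surviving copies, or `NULL` when fewer than two
#'   survive) and `newick` (its newick string, or `NA`).
#' @export
simulate_gene_family <- function(scenario, family_index) {
  sc <- scenario
  stopifnot(inherits(sc, "sim_scenario"), family_index >= 1L)
  set.seed(.family_seed(sc$seed, family_index))
  family_name <- sprintf("fam%04d", as.integer(family_index))
  trait_linked <- .is_trait_linked(sc, family_index)
  stree <- sc$species_tree
  n <- ape::Ntip(stree)
  nn <- n + stree$Nnode
  children <- .children_list(stree)
  blen <- numeric(nn)
  blen[stree$edge[, 2L]] <- stree$edge.length
  lam <- sc$dup_rate; mu <- sc$loss_rate; rate <- lam + mu

  # One Bernoulli draw per trait branch per family, predrawn so the event
  # applies to all copies entering the branch and the stream stays
  # deterministic whether or not any copy reaches it.
  forced_on <- logical(nn)
  if (trait_linked && length(sc$trait_nodes))
    forced_on[sc$trait_nodes] <- stats::runif(length(sc$trait_nodes)) < sc$p_forced_loss

  env <- new.env(parent = emptyenv())
  env$counter <- 0L
  env$events <- list()
  env$forced_logged <- logical(nn)
  env$copies <- stats::setNames(integer(n), stree$tip.label)

  log_event <- function(node, event, time) {
    env$events[[length(env$events) + 1L]] <-
      data.frame(branch = if (node <= n) stree$tip.label[node]
                          else paste0("node", node),
                 node = node, event = event, time = time,
                 stringsAsFactors = FALSE)
  }

  # A copy alive at species node `node` (having survived the branch above
  # it): at a tip it is a surviving gene; at an internal node it speciates
  # into every child branch.
  at_node <- function(node) {
    if (node <= n) {
      env$counter <- env$counter + 1L
      sp <- stree$tip.label[node]
      env$copies[sp] <- env$copies[sp] + 1L
      return(paste0(sp, sc$sep, family_name, "_g", env$counter))
    }
    subs <- character(0)
    for (chn in children[[node]]) {
      s <- bd_copy(chn, 0, blen[chn], forced_on[chn])
      if (!is.null(s)) subs <- c(subs, s)
    }
    if (length(subs) == 0L) return(NULL)
    if (length(subs) == 1L) return(subs)
    paste0("(", paste(subs, collapse = ","), ")")
  }

  # One copy entering the branch above `cnode` at time `t` (0 = branch top).
  # Under a forced loss the horizon is the branch midpoint, past which every
  # copy dies.
  bd_copy <- function(cnode, t, L, forced) {
    H <- if (forced) L / 2 else L
    w <- if (rate > 0) stats::rexp(1L, rate) else Inf
    if (t + w >= H) {
      if (forced) {
        if (!env$forced_logged[cnode]) {
          env$forced_logged[cnode] <- TRUE
          log_event(cnode, "forced_loss", H)
        }
        return(NULL)
      }
      return(at_node(cnode))
    }
    t <- t + w
    if (stats::runif(1L) < lam / rate) {
      log_event(cnode, "dup", t)
      a <- bd_copy(cnode, t, L, forced)
      b <- bd_copy(cnode, t, L, forced)
      if (is.null(a)) return(b)
      if (is.null(b)) return(a)
      return(paste0("(", a, ",", b, ")"))
    }
    log_event(cnode, "loss", t)
    NULL
  }

  nwk <- at_node(n + 1L)
  events <- if (length(env$events)) do.call(rbind, env$events)
            else data.frame(branch = character(0), node = integer(0),
                            event = character(0), time = numeric(0),
                            stringsAsFactors = FALSE)
  gt <- NULL
  newick <- NA_character_
  if (env$counter >= 2L) {
    newick <- paste0(nwk, ";")
    gt <- gene_tree(read_newick(newick, rootedness_hint = "rooted"),
                    sep = sc$sep, family_name = family_name, rooted = TRUE)
  } else if (env$counter == 1L) {
    newick <- paste0(nwk, ";")
  }
  structure(list(family_name = family_name, trait_linked = trait_linked,
                 true_presence = env$copies > 0L, copy_number = env$copies,
                 events = events, gene_tree = gt, newick = newick),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulated family '%s'%s: %d surviving copies in %d/%d species, %d event(s)\n",
              x$family_name, if (x$trait_linked) " (trait-linked)" else "",
              sum(x$copy_number), sum(x$true_presence),
              length(x$true_presence), nrow(x$events)))
  invisible(x)
}

#' Apply per-species detection dropout to simulated truth
#'
#' Each truly present (family, species) cell is observed with probability
#' `completeness[species]`, emulating incomplete genome/transcriptome
#' recovery; absences stay absent. Provenance of observed-present cells is
#' set to a single simulated evidence source (`source`), so two independent
#' sources can be simulated by calling twice with different seeds.
#'
#' @param truths List of `sim_truth` objects.
#' @param completeness Scalar or named per-species vector in `[0,1]`.
#' @param seed Integer seed for the dropout draws.
#' @param source Provenance label, `"tree"` (default) or `"graph"`.
#' @return An `occurrence_matrix` (families x species).
#' @export
apply_detection_noise <- function(truths, completeness, seed,
                                  source = c("tree", "graph")) {
  source <- match.arg(source)
  if (length(truths) == 0L)
    return(occurrence_matrix(matrix(logical(0), 0L, 0L)))
  species <- names(truths[[1L]]$true_presence)
  cs <- .completeness_vector(completeness, species)
  set.seed(seed)
  pres <- matrix(FALSE, length(truths), length(species),
                 dimnames = list(vapply(truths, `[[`, character(1L),
                                        "family_name"),
                                 species))
  for (i in seq_along(truths))
    pres[i, ] <- truths[[i]]$true_presence &
      (stats::runif(length(species)) < cs)
  prov <- matrix(ifelse(pres, source, "none"), nrow(pres),
                 dimnames = dimnames(pres))
  occurrence_matrix(pres, prov)
}

#' Simulate a complete synthetic dataset
#'
#' Orchestrates [simulate_gene_family()] over all family indices and
#' [apply_detection_noise()] over the resulting truth, optionally writing
#' `species.nwk`, one `fam_*.nwk` per surviving gene tree, `truth.tsv`,
#' `observed.tsv` (+ provenance companion) and `manifest.json` to `out_dir`.
#' Fully reproducible: the same scenario and seed yield byte-identical files.
#'
#' @param scenario A `sim_scenario`.
#' @param out_dir Optional output directory (created if missing).
#' @return Invisibly, a list with `truths`, `gene_trees` (named list of the
#'   families with >= 2 surviving copies), `observed` (an
#'   `occurrence_matrix`) and `manifest`.
#' @export
simulate_dataset <- function(scenario, out_dir = NULL) {
  sc <- scenario
  stopifnot(inherits(sc, "sim_scenario"))
  truths <- lapply(seq_len(sc$n_families), function(i)
    simulate_gene_family(sc, i))
  gene_trees <- Filter(Negate(is.null), lapply(truths, `[[`, "gene_tree"))
  names(gene_trees) <- vapply(gene_trees, `[[`, character(1L), "family_name")
  observed <- apply_detection_noise(truths, sc$completeness,
                                    seed = .family_seed(sc$seed, 0L))
  species <- sc$species_tree$tip.label
  manifest <- list(
    n_families = sc$n_families,
    n_species = length(species),
    species = species,
    dup_rate = sc$dup_rate, loss_rate = sc$loss_rate,
    p_forced_loss = sc$p_forced_loss,
    frac_trait_linked = sc$frac_trait_linked,
    trait_loss_branches = sc$trait_loss_branches,
    completeness = as.list(sc$completeness),
    seed = sc$seed, sep = sc$sep)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ape::write.tree(sc$species_tree, file.path(out_dir, "species.nwk"))
    for (gt in gene_trees)
      ape::write.tree(gt$phy,
                      file.path(out_dir, paste0(gt$family_name, ".nwk")))
    truth_df <- data.frame(
      family = vapply(truths, `[[`, character(1L), "family_name"),
      trait_linked = vapply(truths, `[[`, logical(1L), "trait_linked"),
      stringsAsFactors = FALSE)
    pres <- t(vapply(truths, function(x) as.integer(x$true_presence),
                     integer(length(species))))
    colnames(pres) <- species
    if (length(truths))
      truth_df <- cbind(truth_df, as.data.frame(pres))
    utils::write.table(truth_df, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_occurrence_table(observed, file.path(out_dir, "observed.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(truths = truths, gene_trees = gene_trees,
                 observed = observed, manifest = manifest))
}
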