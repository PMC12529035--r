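# Anchor-based orthogroup extraction from rooted gene trees, and ingestion
# of graph-based orthogroup cluster tables as a second evidence source.

#' Define an anchor set
#'
#' Named genes are anchored by the gene ids of their orthologs in one or more
#' reference species (e.g. Medicago truncatula / rice ids for the canonical
#' AM symbiosis gene set); the outgroup species delimits orthogroup clades as
#' the basalmost lineage.
#'
#' @param anchors Named list: gene name -> character vector of anchor gene
#'   ids (each with >= 1 id).
#' @param reference_species Character vector of reference species ids
#'   (metadata).
#' @param outgroup_species Taxon id of the outgroup used as basalmost
#'   ortholog (default the basal angiosperm Amborella trichopoda).
#' @return An object of class `anchor_set`.
#' @export
anchor_set <- function(anchors, reference_species = character(0),
                       outgroup_species = "Amborella_trichopoda") {
  stopifnot(is.list(anchors), length(anchors) > 0L,
            !is.null(names(anchors)), all(nzchar(names(anchors))))
  if (any(lengths(anchors) == 0L))
    stop("every gene name needs at least one anchor id")
  anchors <- lapply(anchors, as.character)
  structure(list(anchors = anchors, reference_species = reference_species,
                 outgroup_species = outgroup_species),
            class = "anchor_set")
}

#' Read an anchor table
#'
#' TSV with columns `gene_name`, `anchor_id`, `reference_species`.
#'
#' @param path Path to the TSV file.
#' @param outgroup_species Passed to [anchor_set()].
#' @return An `anchor_set`.
#' @export
read_anchor_table <- function(path,
                              outgroup_species = "Amborella_trichopoda") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_name", "anchor_id", "reference_species")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("anchor table lacks column(s): ", paste(miss, collapse = ", "))
  anchor_set(split(df$anchor_id, df$gene_name)[unique(df$gene_name)],
             reference_species = unique(df$reference_species),
             outgroup_species = outgroup_species)
}

#' An orthogroup membership call from one evidence source
#'
#' @param gene_name Name of the symbiosis gene (may be `NA` for ad hoc
#'   extractions).
#' @param source Evidence source, `"tree"` or `"graph"`.
#' @param members Character vector of member gene ids.
#' @param species Character vector of member species ids.
#' @param subtree_node Gene-tree node id(s) of the extracted clade root
#'   (tree source only).
#' @param outgroup_found Logical: was an outgroup-basal clade found? `NA`
#'   for graph calls or undetected genes.
#' @param anchor_found Logical: was any anchor id present in this source?
#' @param anchors_used Anchor ids actually matched.
#' @param cluster_id Cluster id (graph source only).
#' @return An object of class `orthogroup_call`.
#' @export
orthogroup_call <- function(gene_name, source, members, species,
                            subtree_node = NA_integer_,
                            outgroup_found = NA, anchor_found = TRUE,
                            anchors_used = character(0),
                            cluster_id = NA_character_) {
  source <- match.arg(source, c("tree", "graph"))
  structure(list(gene_name = gene_name, source = source,
                 members = as.character(members),
                 species = as.character(species),
                 subtree_node = subtree_node,
                 outgroup_found = outgroup_found,
                 anchor_found = anchor_found,
                 anchors_used = as.character(anchors_used),
                 cluster_id = cluster_id),
            class = "orthogroup_call")
}

#' @export
print.orthogroup_call <- function(x, ...) {
  cat(sprintf("Orthogroup call%s [%s]: %d member(s) in %d species%s\n",
              if (is.na(x$gene_name)) "" else paste0(" for ", x$gene_name),
              x$source, length(x$members), length(x$species),
              if (isTRUE(x$outgroup_found)) ""
              else if (isFALSE(x$outgroup_found)) " (no basal outgroup)"
              else ""))
  invisible(x)
}

#' Extract the phylogenetic orthogroup containing anchor genes
#'
#' Starting from each anchor leaf of a rooted gene tree, ascends toward the
#' root and returns the smallest clade that contains the anchor and has at
#' least one child subtree composed exclusively of outgroup-species leaves
#' (the outgroup positioned as the basal lineage of the clade). All leaves
#' of that clade become members -- lineage-specific duplicates included.
#' With several matched anchors the union of their clades is taken.
#'
#' If no such clade exists on the path to the root (common for families
#' where the outgroup copy was not recovered), the whole tree is returned
#' with `outgroup_found = FALSE` rather than dropping the family, so
#' downstream presence calls are not biased toward absence. If no anchor id
#' occurs in the tree the gene is undetected by this evidence source:
#' the call has empty membership and `anchor_found = FALSE`.
#'
#' @param gtree A rooted `gene_tree`.
#' @param anchors Character vector of anchor gene ids.
#' @param outgroup_species Taxon id of the outgroup species.
#' @param gene_name Optional gene name recorded on the call.
#' @return An `orthogroup_call` with `source = "tree"`.
#' @export
extract_orthogroup <- function(gtree, anchors, outgroup_species,
                               gene_name = NA_character_) {
  stopifnot(inherits(gtree, "gene_tree"))
  if (!gtree$rooted)
    stop("orthogroup extraction requires a rooted gene tree")
  lv <- gtree$leaves
  hit <- lv$gene_id %in% anchors
  if (!any(hit))
    return(orthogroup_call(gene_name, "tree", character(0), character(0),
                           outgroup_found = NA, anchor_found = FALSE))
  phy <- gtree$phy
  n <- ape::Ntip(phy)
  root <- n + 1L
  parent <- integer(n + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  ch <- .children_list(phy)
  # all_out[v]: subtree at v consists only of outgroup-species leaves
  all_out <- rep(TRUE, n + phy$Nnode)
  all_out[seq_len(n)] <- lv$species_id == outgroup_species
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; v <- po$edge[i, 2L]
    all_out[p] <- all_out[p] && all_out[v]
  }
  clade_roots <- integer(0)
  for (tip in which(hit)) {
    v <- tip
    repeat {
      v <- parent[v]
      if (any(all_out[ch[[v]]])) { clade_roots <- c(clade_roots, v); break }
      if (v == root) break
    }
  }
  outgroup_found <- length(clade_roots) > 0L
  if (!outgroup_found) clade_roots <- root
  clade_roots <- unique(clade_roots)
  member_labels <- unique(unlist(lapply(clade_roots, .tips_under, phy = phy)))
  keep <- lv[match(member_labels, lv$label), ]
  orthogroup_call(gene_name, "tree",
                  members = keep$gene_id,
                  species = unique(keep$species_id),
                  subtree_node = clade_roots,
                  outgroup_found = outgroup_found,
                  anchor_found = TRUE,
                  anchors_used = intersect(lv$gene_id, anchors))
}

#' Ingest a graph-based orthogroup cluster table
#'
#' For each named gene, every cluster containing at least one of its anchor
#' ids yields one `orthogroup_call` (source `"graph"`). A cluster holding
#' anchors of two gene names yields a call for each (shared membership), and
#' a gene split across clusters yields multiple calls whose union is taken
#' downstream -- mirroring the many-to-many situations that arise in
#' practice between named genes and graph clusters.
#'
#' @param table Data frame with columns `orthogroup_id`, `gene_id`,
#'   `species_id`. A gene id may appear in at most one orthogroup.
#' @param anchor_set An `anchor_set`.
#' @return A list of `orthogroup_call` objects (possibly several per gene
#'   name; genes with no anchored cluster yield one call with
#'   `anchor_found = FALSE`).
#' @export
ingest_graph_clusters <- function(table, anchor_set) {
  stopifnot(inherits(anchor_set, "anchor_set"))
  need <- c("orthogroup_id", "gene_id", "species_id")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("cluster table lacks column(s): ", paste(miss, collapse = ", "))
  og_per_gene <- tapply(table$orthogroup_id, table$gene_id,
                        function(x) length(unique(x)))
  bad <- names(og_per_gene)[og_per_gene > 1L]
  if (length(bad))
    stop("gene id(s) appear in more than one orthogroup: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  calls <- list()
  for (gn in names(anchor_set$anchors)) {
    a <- anchor_set$anchors[[gn]]
    ogs <- sort(unique(table$orthogroup_id[table$gene_id %in% a]))
    if (length(ogs) == 0L) {
      calls[[length(calls) + 1L]] <-
        orthogroup_call(gn, "graph", character(0), character(0),
                        anchor_found = FALSE)
      next
    }
    for (og in ogs) {
      rows <- table[table$orthogroup_id == og, , drop = FALSE]
      calls[[length(calls) + 1L]] <-
        orthogroup_call(gn, "graph", rows$gene_id, unique(rows$species_id),
                        anchor_found = TRUE,
                        anchors_used = intersect(rows$gene_id, a),
                        cluster_id = og)
    }
  }
  calls
}

#' Per-species presence vector of one orthogroup call
#'
#' @param call An `orthogroup_call`.
#' @param all_species Character vector of all species under study.
#' @return Named logical vector over `all_species`; `TRUE` iff at least one
#'   member gene belongs to that species. Multiple calls for one gene
#'   combine downstream by element-wise OR.
#' @export
species_presence <- function(call, all_species) {
  stopifnot(inherits(call, "orthogroup_call"))
  stats::setNames(all_species %in% call$species, all_species)
}
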