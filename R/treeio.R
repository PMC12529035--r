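#' Read a tree in Newick format
#'
#' Thin wrapper around [ape::read.tree()] that additionally records whether
#' the tree is rooted. A tree whose basal node has three or more children is
#' treated as unrooted under `rootedness_hint = "auto"`; an explicit hint
#' overrides the classification (a rooted species tree may legitimately carry
#' a basal polytomy).
#'
#' Quoted labels and internal-node labels are accepted; NHX-style comments in
#' square brackets are stripped before parsing, since inputs may come from a
#' variety of external tree tools.
#'
#' @param text A newick string. Exactly one of `text` and `file` must be
#'   supplied.
#' @param file Path to a newick file containing a single tree.
#' @param rootedness_hint One of `"auto"`, `"rooted"`, `"unrooted"`.
#' @return An `ape::phylo` object with a logical attribute `"rooted"`.
#' @examples
#' phy <- read_newick("((A,B),(C,D));")
#' attr(phy, "rooted")
#' @export
read_newick <- function(text = NULL, file = NULL,
                        rootedness_hint = c("auto", "rooted", "unrooted")) {
  rootedness_hint <- match.arg(rootedness_hint)
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- gsub("\\[[^]]*\\]", "", text) # drop NHX / comment blocks
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed newick string")
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) stop("expected a single tree, found ", length(phy))
    phy <- phy[[1L]]
  }
  basal_degree <- sum(phy$edge[, 1L] == ape::Ntip(phy) + 1L)
  attr(phy, "rooted") <- switch(rootedness_hint,
    rooted   = TRUE,
    unrooted = FALSE,
    auto     = basal_degree == 2L)
  phy
}

#' Validate a species tree
#'
#' Checks the invariants required of the reference species tree: at least two
#' leaves, unique leaf names, non-negative branch lengths. Polytomies are
#' permitted (the LCA stays well defined). The tree is treated as rooted;
#' reading with `rootedness_hint = "unrooted"` is rejected.
#'
#' @param phy An `ape::phylo` object (e.g. from [read_newick()]).
#' @return The validated `phylo`, invisibly classed as before.
#' @export
species_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (ape::Ntip(phy) < 2L) stop("a species tree needs at least 2 leaves")
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stop("duplicate leaf names in species tree: ", paste(dup, collapse = ", "))
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("negative branch lengths in species tree")
  r <- attr(phy, "rooted")
  if (!is.null(r) && !r)
    stop("species tree must be rooted")
  attr(phy, "rooted") <- TRUE
  phy
}

#' Parse gene-tree leaf labels into species and gene ids
#'
#' Leaf labels pack a species id and a gene id into one newick label,
#' by default as `"<species>|<gene_id>"`. The label is split at the *first*
#' occurrence of the separator, so gene ids may contain it but species ids
#' may not.
#'
#' @param label Character vector of leaf labels.
#' @param sep Separator string (default `"|"`).
#' @return A data frame with columns `label`, `species_id`, `gene_id`.
#' @examples
#' parse_leaf_label("Cephalotus_follicularis|Cfol_v3_20843")
#' @export
parse_leaf_label <- function(label, sep = "|") {
  pos <- regexpr(sep, label, fixed = TRUE)
  bad <- pos < 0L
  if (any(bad))
    stop("leaf label(s) lack the '", sep, "' separator: ",
         paste(utils::head(label[bad], 5L), collapse = ", "))
  data.frame(
    label      = label,
    species_id = substr(label, 1L, pos - 1L),
    gene_id    = substr(label, pos + nchar(sep), nchar(label)),
    stringsAsFactors = FALSE)
}

#' Format a species/gene pair as a leaf label
#'
#' Inverse of [parse_leaf_label()] for species ids free of the separator.
#'
#' @param species_id,gene_id Character vectors (recycled).
#' @param sep Separator string.
#' @return Character vector of labels.
#' @export
format_leaf_label <- function(species_id, gene_id, sep = "|") {
  if (any(grepl(sep, species_id, fixed = TRUE)))
    stop("species ids may not contain the separator '", sep, "'")
  paste0(species_id, sep, gene_id)
}

#' Construct a gene tree
#'
#' Wraps an `ape::phylo` whose tip labels follow the `species|gene_id`
#' convention, parsing them into a leaf table. Gene ids must be unique within
#' the tree.
#'
#' @param phy An `ape::phylo` with >= 2 tips.
#' @param sep Leaf-label separator.
#' @param family_name Name of the gene family.
#' @param rooted Logical; if `NULL`, taken from the `"rooted"` attribute of
#'   `phy`, falling back to basal degree 2.
#' @return An object of class `gene_tree`: a list with elements `phy`,
#'   `leaves` (data frame label/species_id/gene_id), `family_name`, `rooted`,
#'   `sep`.
#' @export
gene_tree <- function(phy, sep = "|", family_name = "family", rooted = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (ape::Ntip(phy) < 2L) stop("a gene tree needs at least 2 leaves")
  leaves <- parse_leaf_label(phy$tip.label, sep)
  dup <- unique(leaves$gene_id[duplicated(leaves$gene_id)])
  if (length(dup))
    stop("duplicate gene ids in gene tree '", family_name, "': ",
         paste(dup, collapse = ", "))
  if (is.null(rooted)) {
    r <- attr(phy, "rooted")
    rooted <- if (is.null(r))
      sum(phy$edge[, 1L] == ape::Ntip(phy) + 1L) == 2L else r
  }
  structure(list(phy = phy, leaves = leaves, family_name = family_name,
                 rooted = rooted, sep = sep),
            class = "gene_tree")
}

#' Read a gene tree from newick
#'
#' @inheritParams read_newick
#' @inheritParams gene_tree
#' @param stree Optional species tree; if given, leaves whose species is not
#'   a leaf of `stree` are pruned with a warning (see [prune_to_species()]).
#' @return A `gene_tree`.
#' @export
read_gene_tree <- function(text = NULL, file = NULL, sep = "|",
                           family_name = "family",
                           rootedness_hint = "auto", stree = NULL) {
  phy <- read_newick(text = text, file = file, rootedness_hint = rootedness_hint)
  gt <- gene_tree(phy, sep = sep, family_name = family_name)
  if (!is.null(stree)) gt <- prune_to_species(gt, stree)
  gt
}

#' Prune gene-tree leaves whose species is absent from the species tree
#'
#' Leaves that cannot be mapped onto the species tree (e.g. contaminant
#' sequences left over from upstream assembly) are dropped with a warning
#' listing the offending species.
#'
#' @param gt A `gene_tree`.
#' @param stree A species tree (`phylo`).
#' @return The pruned `gene_tree` (unchanged if nothing to prune).
#' @export
prune_to_species <- function(gt, stree) {
  stopifnot(inherits(gt, "gene_tree"))
  bad <- !(gt$leaves$species_id %in% stree$tip.label)
  if (!any(bad)) return(gt)
  warning(sprintf(
    "pruning %d leaf/leaves of '%s' with species absent from the species tree: %s",
    sum(bad), gt$family_name,
    paste(unique(gt$leaves$species_id[bad]), collapse = ", ")))
  if (sum(!bad) < 2L)
    stop("fewer than 2 leaves remain in '", gt$family_name, "' after pruning")
  phy2 <- ape::drop.tip(gt$phy, gt$leaves$label[bad])
  gene_tree(phy2, sep = gt$sep, family_name = gt$family_name,
            rooted = gt$rooted)
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("Gene tree '%s': %d leaves, %d species, %s\n",
              x$family_name, nrow(x$leaves),
              length(unique(x$leaves$species_id)),
              if (x$rooted) "rooted" else "unrooted"))
  invisible(x)
}

# ---- occurrence matrix container and TSV serialization -----------------------

.PROVENANCE_LEVELS <- c("tree", "graph", "both", "none")

#' Gene-by-species occurrence matrix with evidence provenance
#'
#' The consensus data structure of the pipeline: a logical genes x species
#' presence matrix plus a parallel character matrix recording which evidence
#' source(s) support each present cell (`"tree"`, `"graph"`, `"both"`) with
#' `"none"` for absent cells. The invariant `provenance == "none"` iff
#' `presence == FALSE` is enforced at construction.
#'
#' @param presence Logical matrix with gene row names and species column
#'   names.
#' @param provenance Character matrix of the same shape over
#'   `c("tree","graph","both","none")`. If `NULL`, present cells are
#'   attributed to `"tree"`.
#' @param species_meta Optional data frame of per-species metadata (e.g.
#'   assembly type, clade, trait labels), one row per column.
#' @return An object of class `occurrence_matrix`.
#' @export
occurrence_matrix <- function(presence, provenance = NULL, species_meta = NULL) {
  stopifnot(is.matrix(presence), is.logical(presence))
  if (is.null(rownames(presence))) rownames(presence) <- character(nrow(presence))
  if (is.null(colnames(presence)) && ncol(presence) > 0L)
    stop("presence matrix needs species column names")
  if (is.null(provenance)) {
    provenance <- matrix(ifelse(presence, "tree", "none"),
                         nrow = nrow(presence), dimnames = dimnames(presence))
  }
  stopifnot(is.matrix(provenance), identical(dim(provenance), dim(presence)))
  dimnames(provenance) <- dimnames(presence)
  if (!all(provenance %in% .PROVENANCE_LEVELS))
    stop("provenance values must be one of: ",
         paste(.PROVENANCE_LEVELS, collapse = ", "))
  if (!identical(unname(provenance == "none"), unname(!presence)))
    stop("provenance 'none' must coincide exactly with absent cells")
  structure(list(presence = presence, provenance = provenance,
                 species_meta = species_meta),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("Occurrence matrix: %d gene(s) x %d species; %d present cell(s)\n",
              nrow(x$presence), ncol(x$presence), sum(x$presence)))
  invisible(x)
}

.provenance_path <- function(path) {
  ext <- tools::file_ext(path)
  if (nzchar(ext))
    sub(paste0("\\.", ext, "$"), paste0("_provenance.", ext), path)
  else paste0(path, "_provenance")
}

#' Write an occurrence matrix (and its provenance layer) as TSV
#'
#' The main table has a header row of species ids, one row per gene, and 1/0
#' cells; the companion provenance table mirrors it with cells in
#' `{tree, graph, both, none}`. [read_occurrence_table()] inverts the pair
#' exactly.
#'
#' @param m An `occurrence_matrix`.
#' @param path Output path for the presence table.
#' @param provenance_path Output path for the provenance table; defaults to
#'   `path` with a `_provenance` suffix before the extension.
#' @return `path`, invisibly.
#' @export
write_occurrence_table <- function(m, path,
                                   provenance_path = .provenance_path(path)) {
  stopifnot(inherits(m, "occurrence_matrix"))
  .write_cells <- function(cells, p) {
    df <- data.frame(gene = rownames(cells), stringsAsFactors = FALSE)
    if (ncol(cells) > 0L)
      df <- cbind(df, as.data.frame(cells, stringsAsFactors = FALSE))
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  .write_cells(matrix(as.integer(m$presence), nrow = nrow(m$presence),
                      dimnames = dimnames(m$presence)), path)
  .write_cells(m$provenance, provenance_path)
  invisible(path)
}

#' Read an occurrence matrix written by [write_occurrence_table()]
#'
#' @param path Path to the presence TSV.
#' @param provenance_path Path to the provenance TSV; if the default
#'   companion file does not exist, present cells are attributed to
#'   `"tree"`.
#' @return An `occurrence_matrix`.
#' @export
read_occurrence_table <- function(path,
                                  provenance_path = .provenance_path(path)) {
  .read_cells <- function(p, what) {
    lines <- readLines(p)
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    species <- header[-1L]
    if (length(lines) == 1L) { # header-only: empty matrix
      cells <- matrix(vector(what, 0L), 0L, length(species),
                      dimnames = if (length(species))
                        list(character(0), species) else NULL)
      return(cells)
    }
    df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = c("character",
                                           rep(what, length(species))))
    cells <- as.matrix(df[, -1L, drop = FALSE])
    rownames(cells) <- df$gene
    cells
  }
  pres <- .read_cells(path, "integer")
  mode(pres) <- "logical"
  prov <- if (file.exists(provenance_path))
    .read_cells(provenance_path, "character") else NULL
  occurrence_matrix(pres, prov)
}
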