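# Consensus gene x species occurrence matrix from tree-based and graph-based
# evidence, and retention statistics over it.

.calls_to_presence <- function(calls, all_species, gene_names) {
  P <- matrix(FALSE, length(gene_names), length(all_species),
              dimnames = list(gene_names, all_species))
  for (call in calls) {
    stopifnot(inherits(call, "orthogroup_call"))
    if (is.na(call$gene_name) || !(call$gene_name %in% gene_names)) next
    unknown <- setdiff(call$species, all_species)
    if (length(unknown))
      stop("unknown species id(s) in call for '", call$gene_name, "': ",
           paste(unknown, collapse = ", "))
    P[call$gene_name, ] <- P[call$gene_name, ] |
      species_presence(call, all_species)
  }
  P
}

#' Consensus presence across tree and graph evidence
#'
#' A gene is called present in a species if it is present in *either* the
#' tree-based evidence or the graph-based evidence (union rule); the
#' provenance layer records which source(s) supported each present cell.
#' Multiple calls for one gene within a source are combined by element-wise
#' OR (split orthogroups, multiple anchors).
#'
#' @param tree_calls,graph_calls Lists of `orthogroup_call` objects from the
#'   respective sources (either may be empty).
#' @param all_species Character vector of species columns.
#' @param gene_names Character vector of gene rows, in the desired order
#'   (conventionally the anchor-table order).
#' @return An `occurrence_matrix`.
#' @export
consensus_presence <- function(tree_calls, graph_calls, all_species,
                               gene_names) {
  Pt <- .calls_to_presence(tree_calls, all_species, gene_names)
  Pg <- .calls_to_presence(graph_calls, all_species, gene_names)
  pres <- Pt | Pg
  prov <- matrix("none", nrow(pres), ncol(pres), dimnames = dimnames(pres))
  prov[Pt & !Pg] <- "tree"
  prov[!Pt & Pg] <- "graph"
  prov[Pt & Pg] <- "both"
  occurrence_matrix(pres, prov)
}

#' Retention rate of a gene set in one species
#'
#' Fraction of the gene subset called present in the given species, with the
#' underlying counts; `loss = 1 - retention`.
#'
#' @param matrix An `occurrence_matrix`.
#' @param gene_subset Character vector of row names (default: all rows).
#' @param species_id A single species column name.
#' @return A list with `k` (present count), `n` (subset size), `retention`
#'   (`k/n`) and `loss` (`1 - k/n`).
#' @examples
#' m <- occurrence_matrix(matrix(rep(c(TRUE, FALSE), c(15, 60)),
#'                               dimnames = list(paste0("g", 1:75), "Cfol")))
#' retention_rate(m, species_id = "Cfol") # 15/75 retained, 80% lost
#' @export
retention_rate <- function(matrix, gene_subset = NULL, species_id) {
  stopifnot(inherits(matrix, "occurrence_matrix"))
  if (is.null(gene_subset)) gene_subset <- rownames(matrix$presence)
  if (length(gene_subset) == 0L) stop("empty gene subset")
  miss <- setdiff(gene_subset, rownames(matrix$presence))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  if (length(species_id) != 1L || !(species_id %in% colnames(matrix$presence)))
    stop("species_id must name one matrix column")
  k <- sum(matrix$presence[gene_subset, species_id])
  n <- length(gene_subset)
  list(k = as.integer(k), n = as.integer(n),
       retention = k / n, loss = 1 - k / n)
}

#' Per-species retention summarized by species group
#'
#' @param matrix An `occurrence_matrix`.
#' @param species_groups Named list of disjoint character vectors of species
#'   column names (each nonempty).
#' @param gene_subset Optional row subset (default: all rows).
#' @return A list of two data frames: `per_species` (species, group, k, n,
#'   retention) and `per_group` (group, n_species, mean/min/max retention).
#' @export
summarize_by_group <- function(matrix, species_groups, gene_subset = NULL) {
  stopifnot(inherits(matrix, "occurrence_matrix"),
            is.list(species_groups), length(species_groups) > 0L,
            !is.null(names(species_groups)))
  if (any(lengths(species_groups) == 0L)) stop("empty species group")
  all_sp <- unlist(species_groups, use.names = FALSE)
  if (anyDuplicated(all_sp)) stop("species groups must be disjoint")
  miss <- setdiff(all_sp, colnames(matrix$presence))
  if (length(miss)) stop("unknown species: ", paste(miss, collapse = ", "))
  per_species <- do.call(rbind, lapply(names(species_groups), function(g) {
    do.call(rbind, lapply(species_groups[[g]], function(s) {
      r <- retention_rate(matrix, gene_subset, s)
      data.frame(species = s, group = g, k = r$k, n = r$n,
                 retention = r$retention, stringsAsFactors = FALSE)
    }))
  }))
  per_group <- do.call(rbind, lapply(split(per_species, per_species$group),
    function(d) data.frame(group = d$group[1L], n_species = nrow(d),
                           mean_retention = mean(d$retention),
                           min_retention = min(d$retention),
                           max_retention = max(d$retention),
                           stringsAsFactors = FALSE)))
  rownames(per_group) <- NULL
  list(per_species = per_species, per_group = per_group)
}
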