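# Genome-wide convergent-loss screen: orthogroups absent in every focal
# (e.g. carnivorous) species and present in every background species, with
# overlap and exact hypergeometric enrichment against a target gene list.

#' Screen for convergently lost orthogroups
#'
#' Over a presence/absence matrix (rows: orthogroups or genes; columns:
#' species), finds the rows present in *every* background species and absent
#' in *every* focal species; the hits are their intersection. Undetected is
#' treated as absent, matching the detected/undetected dichotomy of
#' presence-calling pipelines.
#'
#' `focal_species` may also be a list of species sets (one per independent
#' focal lineage); requiring each lineage to be all-absent is equivalent to
#' requiring absence across their union, so the sets are pooled.
#'
#' @param matrix An `occurrence_matrix` or a logical matrix with species
#'   column names.
#' @param focal_species Character vector (or list of vectors) of focal taxon
#'   ids; must be disjoint from `background_species`, both nonempty, and all
#'   present among the matrix columns.
#' @param background_species Character vector of background taxon ids.
#' @return An object of class `screen_result`: `n_universe`,
#'   `n_background_present`, `n_focal_absent`, `hits` (row names satisfying
#'   both), the two component sets, and the species sets used.
#' @export
convergent_loss_screen <- function(matrix, focal_species,
                                   background_species) {
  P <- if (inherits(matrix, "occurrence_matrix")) matrix$presence else matrix
  stopifnot(is.matrix(P), is.logical(P))
  focal <- unique(unlist(focal_species, use.names = FALSE))
  background <- unique(unlist(background_species, use.names = FALSE))
  if (length(focal) == 0L || length(background) == 0L)
    stop("focal and background species sets must be nonempty")
  if (length(intersect(focal, background)))
    stop("focal and background species sets must be disjoint")
  miss <- setdiff(c(focal, background), colnames(P))
  if (length(miss))
    stop("species missing from the matrix: ", paste(miss, collapse = ", "))
  rn <- rownames(P)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(P)))
  bg_present <- rn[rowSums(!P[, background, drop = FALSE]) == 0L]
  focal_absent <- rn[rowSums(P[, focal, drop = FALSE]) == 0L]
  structure(list(n_universe = nrow(P),
                 n_background_present = length(bg_present),
                 n_focal_absent = length(focal_absent),
                 hits = intersect(bg_present, focal_absent),
                 background_present = bg_present,
                 focal_absent = focal_absent,
                 focal_species = focal,
                 background_species = background),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Convergent-loss screen: %d orthogroups; %d present in all %d ",
    "background species; %d absent in all %d focal species; %d hit(s)\n"),
    x$n_universe, x$n_background_present, length(x$background_species),
    x$n_focal_absent, length(x$focal_species), length(x$hits)))
  invisible(x)
}

#' Overlap of screen hits with a target gene list
#'
#' @param result A `screen_result`.
#' @param target_ids Character vector of target orthogroup/gene ids.
#' @return A list with `k` (overlap count) and `ids` (the overlapping ids).
#' @export
overlap_with_target <- function(result, target_ids) {
  stopifnot(inherits(result, "screen_result"))
  ids <- intersect(result$hits, target_ids)
  list(k = length(ids), ids = ids)
}

#' Exact one-sided hypergeometric enrichment
#'
#' Upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`: drawing `n` items without replacement from
#' a universe of `N` containing `K` targets. Computed by exact summation of
#' the hypergeometric mass over the tail. One-sided (over-representation);
#' apply [stats::p.adjust()] externally for multiple target lists.
#'
#' @param k Observed overlap count.
#' @param K Number of targets in the universe.
#' @param n Number of draws (e.g. screen hits).
#' @param N Universe size.
#' @return The exact tail probability.
#' @examples
#' hypergeometric_enrichment(4, 5, 4, 10) # 5/210
#' @export
hypergeometric_enrichment <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L,
            length(N) == 1L)
  if (!(k >= 0 && K >= 0 && n >= 0 && N >= 0 && K <= N && n <= N &&
        k <= min(K, n)))
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N and K, n <= N")
  if (k == 0) return(1)
  sum(stats::dhyper(seq(k, min(K, n)), K, N - K, n))
}
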