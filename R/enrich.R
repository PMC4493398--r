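#' Read gene sets in GMT format
#'
#' Thin wrapper over `fgsea::gmtPathways()`; returns a named list of gene-id
#' vectors.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) stop("gene-set names must be unique")
  sets
}

#' Hypergeometric over-representation test for a gene list
#'
#' Exact hypergeometric upper tail P(X >= k) of the overlap k between the
#' query list and each gene set, within a background universe, followed by
#' Benjamini-Hochberg correction across sets. Gene sets are intersected
#' with the universe; query genes outside the universe are dropped with a
#' warning. This is a plain over-representation test, not a reimplementation
#' of DAVID's EASE score or functional clustering.
#'
#' @param query character vector of query gene ids.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe background gene ids (default: union of all sets).
#' @param p_cutoff results with `p_value <= p_cutoff` are flagged
#'   significant.
#' @return data.frame sorted by p-value: `set`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, `significant`.
#' @export
hypergeom_enrich <- function(query, gene_sets,
                             universe = unique(unlist(gene_sets)),
                             p_cutoff = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("background universe is empty")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) not in universe; dropped")
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)
  res <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  }))
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$set), ]
  res$significant <- res$p_value <= p_cutoff
  rownames(res) <- NULL
  res
}
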