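#' One-sided Fisher's exact (hypergeometric) term enrichment
#'
#' For every term annotated to at least one cluster gene, the enrichment
#' p-value is the hypergeometric upper tail P(X >= k) of drawing k term
#' genes in a cluster of size n from a universe of N genes of which K carry
#' the term (computed via [stats::phyper()], which works in log space).
#' Benjamini-Hochberg q-values are appended; the raw p is the primary
#' statistic.
#'
#' @param cluster character vector of gene ids (must be a subset of
#'   `universe`)
#' @param universe character vector: the gene universe (genes surviving
#'   preprocessing, i.e. "on the array")
#' @param annotations tibble/data.frame with columns `gene_id`, `term_id`
#'   (flat annotation pairs; no ontology propagation is performed)
#' @return tibble with columns term_id, k, n, K, N, p, q, sorted by p
#' @export
fisher_enrichment <- function(cluster, universe, annotations) {
  cluster <- unique(as.character(cluster))
  universe <- unique(as.character(universe))
  if (!all(cluster %in% universe)) {
    stop("cluster must be a subset of the universe")
  }
  ann <- as_tibble(annotations) %>%
    filter(gene_id %in% universe) %>%
    distinct(gene_id, term_id)
  N_u <- length(universe)
  n_cl <- length(cluster)
  in_cluster <- ann %>%
    filter(gene_id %in% cluster) %>%
    group_by(term_id) %>%
    summarise(k = n(), .groups = "drop")
  if (nrow(in_cluster) == 0) {
    return(tibble(
      term_id = character(0), k = integer(0), n = integer(0),
      K = integer(0), N = integer(0), p = numeric(0), q = numeric(0)
    ))
  }
  in_universe <- ann %>%
    group_by(term_id) %>%
    summarise(K = n(), .groups = "drop")
  res <- left_join(in_cluster, in_universe, by = "term_id") %>%
    mutate(
      n = n_cl, N = N_u,
      p = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    ) %>%
    arrange(p, term_id) %>%
    mutate(q = p.adjust(p, method = "BH")) %>%
    select(term_id, k, n, K, N, p, q)
  res
}
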