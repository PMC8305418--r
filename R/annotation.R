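#' Filter drug-gene interactions to druggable modes of action
#'
#' Keeps interaction rows whose gene is in the query set and whose mode of
#' action is in the filter vocabulary (by default inhibitor, antagonist,
#' modulator). The manual curation category is a pass-through annotation and
#' is never inferred. The result is invariant to row order and to the case
#' of the interaction type.
#'
#' @param table A `DrugGeneTable` data frame (see [read_interactions_tsv()]).
#' @param genes Character vector of genes of interest.
#' @param modes Mode-of-action vocabulary to retain.
#' @return List with `interactions` (kept rows, original order) and
#'   `druggable_genes` (sorted distinct genes with at least one kept row).
#' @export
filter_druggable <- function(table, genes,
                             modes = c("inhibitor", "antagonist", "modulator")) {
  stopifnot(is.data.frame(table))
  keep <- table$gene_symbol %in% genes &
    tolower(table$interaction_type) %in% tolower(modes)
  kept <- table[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(interactions = kept,
       druggable_genes = sort(unique(kept$gene_symbol)))
}

#' Hypergeometric pathway enrichment with Benjamini-Hochberg correction
#'
#' For each pathway, the upper-tail hypergeometric probability of observing
#' an overlap with the query set at least as large as the one seen, given
#' the pathway size, query size and universe size. P values are adjusted
#' across all tested pathways by Benjamini-Hochberg; a pathway is flagged
#' significant when the adjusted p is at or below `alpha`. Query genes
#' outside the universe are dropped with a warning; pathway members outside
#' the universe do not count.
#'
#' @param genes Query gene set.
#' @param pathways Named list of pathway member gene vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Background gene set (explicit; there is no sensible
#'   default).
#' @param alpha Significance level on the adjusted p value.
#' @return Data frame of class `EnrichmentResult`, ordered by adjusted p
#'   then pathway id: `pathway`, `pathway_size`, `overlap`, `expected`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
enrich <- function(genes, pathways, universe, alpha = 0.05) {
  stopifnot(length(universe) > 0)
  universe <- unique(universe)
  outside <- setdiff(genes, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped")
  }
  q <- intersect(unique(genes), universe)
  N <- length(universe)
  n <- length(q)
  res <- lapply(names(pathways), function(id) {
    mem <- intersect(unique(pathways[[id]]), universe)
    K <- length(mem)
    k <- length(intersect(mem, q))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = id, pathway_size = K, overlap = k,
               expected = n * K / N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted <= alpha
  out <- out[order(out$p_adjusted, out$pathway), ]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}
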