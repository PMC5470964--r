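#' Gene-set over-representation test
#'
#' One-sided hypergeometric upper-tail test (equivalent to a one-sided
#' Fisher exact test) for over-representation of a gene set within a
#' differential gene list, against a stated universe — e.g. imprinted
#' genes among the RT-overexpressed list, with the universe being the
#' genes that survived [filter_genes()]. The gene set is intersected with
#' the universe before testing.
#'
#' @param de_genes Character vector, the differential list (must be a
#'   subset of `universe`).
#' @param gene_set Character vector, the annotated set (e.g. imprinted
#'   genes).
#' @param universe Character vector of all tested genes.
#' @return A tibble with `universe_size` (N), `set_size` (K), `list_size`
#'   (n), `overlap` (k), `expected`, `fold_enrichment` and `p_value`
#'   (`P(X >= k)`).
#' @export
#' @examples
#' overrepresentation_test(letters[1:5], letters[1:5], letters[1:10])
overrepresentation_test <- function(de_genes, gene_set, universe) {
  universe <- unique(universe)
  de_genes <- unique(de_genes)
  if (!length(universe)) abort("empty universe")
  if (!length(de_genes)) abort("empty differential list")
  if (!all(de_genes %in% universe)) {
    abort("de_genes must be a subset of the universe")
  }
  set_u <- intersect(unique(gene_set), universe)
  N <- length(universe)
  K <- length(set_u)
  n <- length(de_genes)
  k <- length(intersect(de_genes, set_u))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(
    universe_size = N, set_size = K, list_size = n, overlap = k,
    expected = n * K / N,
    fold_enrichment = if (K == 0) NA_real_ else (k / n) / (K / N),
    p_value = p
  )
}
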