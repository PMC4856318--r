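#' Hypergeometric (one-sided Fisher) gene-set enrichment
#'
#' Tests whether a gene set is over-represented among a selected set of genes
#' (e.g. the top-scoring perturbed genes) drawn from a universe.  With
#' `N = |universe|`, `K` genes of the set in the universe, `n` selected genes
#' and `k` of them in the set, the p-value is the upper tail
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` — the one-sided Fisher's
#' exact test.  Identifiers are compared case-insensitively after whitespace
#' stripping.
#'
#' @param selected character vector of selected genes (must lie in
#'   `universe`).
#' @param geneset character vector; intersected with the universe before
#'   testing.
#' @param universe character vector of all eligible genes.
#' @return object of class `enrichment_result`: list with `k`, `K`, `n`,
#'   `N`, `fold` (`(k/n)/(K/N)`, 0 when `k = 0`) and `pvalue`.
#' @export
hypergeometric_enrichment <- function(selected, geneset, universe) {
  norm_ids <- function(x) unique(toupper(trimws(as.character(x))))
  universe <- norm_ids(universe)
  selected <- norm_ids(selected)
  geneset <- norm_ids(geneset)
  if (length(universe) == 0) stop("empty universe")
  if (length(selected) == 0) stop("empty selected set")
  outside <- setdiff(selected, universe)
  if (length(outside) > 0)
    stop("selected gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  geneset <- intersect(geneset, universe)
  N <- length(universe)
  K <- length(geneset)
  n <- length(selected)
  k <- length(intersect(selected, geneset))
  pvalue <- if (K == 0) 1 else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (k == 0) 0 else (k / n) / (K / N)
  structure(list(k = k, K = K, n = n, N = N, fold = fold, pvalue = pvalue),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: %d/%d selected in gene set (%d/%d in universe), fold %.2f, p = %.3g\n",
    x$k, x$n, x$K, x$N, x$fold, x$pvalue))
  invisible(x)
}
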