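#' Read a GMT gene-set file
#'
#' Thin wrapper over [fgsea::gmtPathways()].
#'
#' @param path path to a tab-delimited GMT file (set name, description,
#'   member genes).
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("cannot open GMT file: ", path)
  fgsea::gmtPathways(path)
}

#' Hypergeometric term over-representation with BH FDR
#'
#' For every term, tests whether the selection contains more term members
#' than expected by chance under sampling without replacement from the
#' universe: the upper-tail hypergeometric probability `P[X >= k]` with `k`
#' selected term members, `K` term members in the universe, `n` selected
#' genes, and `N` universe genes. P-values are Benjamini-Hochberg adjusted
#' across the tested terms; a term is enriched when its adjusted p-value is
#' below `alpha`.
#'
#' @param selection character vector of selected gene ids (e.g. SDATs); must
#'   be a subset of `universe`.
#' @param terms named list of gene-id vectors (term -> member genes).
#' @param universe character vector of all assayed gene ids.
#' @param alpha adjusted-p threshold for the `enriched` flag (default 0.05).
#' @return data.frame with term, k, K, n, N, p, p_adj, enriched; zero rows
#'   when the selection is empty.
#' @export
hypergeom_enrich <- function(selection, terms, universe, alpha = 0.05) {
  selection <- unique(selection)
  universe <- unique(universe)
  if (!all(selection %in% universe))
    stop("selection must be a subset of the universe")
  if (length(selection) == 0)
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), enriched = logical(0)))
  N <- length(universe)
  n <- length(selection)
  res <- data.frame(
    term = names(terms),
    k = vapply(terms, function(g) length(intersect(unique(g), selection)), 0L),
    K = vapply(terms, function(g) length(intersect(unique(g), universe)), 0L),
    n = n, N = N, stringsAsFactors = FALSE, row.names = NULL)
  res$p <- stats::phyper(res$k - 1, res$K, res$N - res$K, res$n,
                         lower.tail = FALSE)
  res$p_adj <- bh_fdr(res$p)
  res$enriched <- res$p_adj < alpha
  res
}
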