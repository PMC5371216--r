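#' Quantile normalisation
#'
#' Forces every column of a matrix onto the same distribution: each value is
#' replaced by the mean, across columns, of the values holding the same rank
#' (the row-wise means of the column-sorted matrix). Within-column rank order
#' is preserved. Ties are resolved by averaging the reference values over the
#' tied ranks.
#'
#' @param m numeric matrix, probes (or genes) x arrays.
#' @return A matrix of the same shape; in the absence of ties all columns
#'   share an identical multiset of values.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 1 || nrow(m) < 1) stop("matrix must be non-empty")
  if (!all(is.finite(m))) stop("matrix must be finite")
  if (ncol(m) == 1) return(m)
  mu <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    (mu[floor(r)] + mu[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Median polish summarisation of a probe block
#'
#' Iteratively sweeps row (probe) and column (array) medians out of a
#' log2-scale probes x arrays block until the largest absolute change of any
#' fitted effect in a full sweep falls below `tol`, or `max_iter` sweeps have
#' run. The per-array gene expression measure is the overall effect plus the
#' array (column) effect, as in RMA summarisation.
#'
#' @param probe_block numeric matrix, probes x arrays, log2 scale.
#' @param max_iter maximum number of row+column sweeps.
#' @param tol convergence tolerance on the maximum absolute change.
#' @return list with `overall`, `row` (probe effects), `col` (array effects),
#'   `residuals`, `expression` (= overall + col, one value per array), and
#'   `iterations`.
#' @export
median_polish_summarize <- function(probe_block, max_iter = 10L,
                                    tol = 1e-6) {
  x <- as.matrix(probe_block)
  if (nrow(x) < 1 || ncol(x) < 1) stop("probe block must be non-empty")
  if (!all(is.finite(x))) stop("probe block must be finite")
  overall <- 0
  row_eff <- rep(0, nrow(x))
  col_eff <- rep(0, ncol(x))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    rmed <- apply(x, 1, stats::median)
    x <- x - rmed
    row_eff <- row_eff + rmed
    cmed_r <- stats::median(row_eff)
    row_eff <- row_eff - cmed_r
    overall <- overall + cmed_r

    cmed <- apply(x, 2, stats::median)
    x <- sweep(x, 2, cmed)
    col_eff <- col_eff + cmed
    rmed_c <- stats::median(col_eff)
    col_eff <- col_eff - rmed_c
    overall <- overall + rmed_c

    delta <- max(abs(c(rmed, cmed, cmed_r, rmed_c)))
    if (delta < tol || iter >= max_iter) break
  }
  expression <- overall + col_eff
  names(expression) <- colnames(probe_block)
  list(overall = overall, row = row_eff, col = col_eff, residuals = x,
       expression = expression, iterations = iter)
}

#' Log2 transform
#'
#' @param m numeric matrix or vector of strictly positive values.
#' @return log2 of the input.
#' @export
log2_transform <- function(m) {
  if (any(!is.finite(m)) || any(m <= 0))
    stop("all values must be positive and finite for log2 transform")
  log2(m)
}

#' Summarise a probe-level matrix into per-gene expression
#'
#' The array-processing path: optional percentile-floor background
#' adjustment, quantile normalisation across arrays, log2 transform, then a
#' per-gene median polish over each gene's probe block (jointly across all
#' arrays). Probe-specific convolution background correction is deliberately
#' not modelled; the `floor` option simply clamps intensities at a low
#' percentile of the whole matrix.
#'
#' @param probes numeric matrix of positive probe intensities
#'   (probes x arrays) with probe ids as rownames; up to a handful of probes
#'   per gene.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`; every
#'   probe maps to exactly one gene.
#' @param background `"none"` (default) or `"floor"`.
#' @param floor_quantile percentile used by the floor background.
#' @param log2_input set TRUE if `probes` is already on the log2 scale
#'   (skips background and the transform; quantile normalisation is still
#'   applied).
#' @param ... passed to [median_polish_summarize()].
#' @return numeric matrix, genes x arrays, log2 expression.
#' @export
summarize_probes <- function(probes, probe_map, background = c("none", "floor"),
                             floor_quantile = 0.01, log2_input = FALSE, ...) {
  background <- match.arg(background)
  probes <- as.matrix(probes)
  if (is.null(rownames(probes))) stop("probes must have probe ids as rownames")
  if (anyDuplicated(probe_map$probe_id))
    stop("every probe must map to exactly one gene")
  if (!all(rownames(probes) %in% probe_map$probe_id))
    stop("unmapped probes in matrix")

  if (!log2_input) {
    if (background == "floor") {
      fl <- stats::quantile(probes, floor_quantile)
      probes <- pmax(probes, fl)
    }
    probes <- log2_transform(quantile_normalize(probes))
  } else {
    probes <- quantile_normalize(probes)
  }

  gene_of <- stats::setNames(probe_map$gene_id, probe_map$probe_id)
  blocks <- split(rownames(probes), gene_of[rownames(probes)])
  genes <- sort(names(blocks))
  out <- t(vapply(genes, function(g) {
    median_polish_summarize(probes[blocks[[g]], , drop = FALSE],
                            ...)$expression
  }, numeric(ncol(probes))))
  dimnames(out) <- list(genes, colnames(probes))
  out
}
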