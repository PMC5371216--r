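#' Delta-delta-Ct log2 relative quantity
#'
#' Relative quantification with an amplification efficiency of 2: the log2
#' relative quantity of the target in a condition versus a calibrator
#' condition is
#' `-[(Ct_target,cond - Ct_ref,cond) - (Ct_target,cal - Ct_ref,cal)]`.
#'
#' @param ct_target_cond,ct_ref_cond target and reference-gene Ct in the
#'   condition of interest.
#' @param ct_target_cal,ct_ref_cal target and reference-gene Ct in the
#'   calibrator condition.
#' @return log2 relative quantity (the linear quantity is `2^value`).
#'   Vectorised.
#' @export
ddct <- function(ct_target_cond, ct_ref_cond, ct_target_cal, ct_ref_cal) {
  args <- cbind(ct_target_cond, ct_ref_cond, ct_target_cal, ct_ref_cal)
  if (any(!is.finite(args))) stop("Ct values must be finite")
  -((ct_target_cond - ct_ref_cond) - (ct_target_cal - ct_ref_cal))
}

#' Per-gene, per-condition qPCR log2 ratios from a Ct table
#'
#' Ct values are averaged over replicates within each gene x condition
#' before the delta-delta-Ct contrast against the calibrator condition; the
#' reference gene is identified by name and normalises every condition.
#'
#' @param ct_table data.frame with columns gene, condition, replicate, Ct
#'   (and optionally is_reference).
#' @param reference_gene name of the stable reference gene.
#' @param calibrator calibrator condition (default `"HYD"`).
#' @return data.frame with gene, comparison (`"<cond>/<calibrator>"`),
#'   log2_ratio, one row per target gene x non-calibrator condition.
#' @export
qpcr_log2_ratios <- function(ct_table, reference_gene, calibrator = "HYD") {
  if (!reference_gene %in% ct_table$gene)
    stop("reference gene '", reference_gene, "' not present in Ct table")
  mean_ct <- tapply(ct_table$Ct, list(ct_table$gene, ct_table$condition),
                    mean)
  if (!calibrator %in% colnames(mean_ct)) stop("calibrator condition absent")
  ref <- mean_ct[reference_gene, ]
  targets <- setdiff(rownames(mean_ct), reference_gene)
  other <- setdiff(colnames(mean_ct), calibrator)
  rows <- expand.grid(gene = targets, condition = other,
                      stringsAsFactors = FALSE)
  rows$log2_ratio <- ddct(
    ct_target_cond = mean_ct[cbind(rows$gene, rows$condition)],
    ct_ref_cond = ref[rows$condition],
    ct_target_cal = mean_ct[rows$gene, calibrator],
    ct_ref_cal = ref[calibrator])
  data.frame(gene = rows$gene,
             comparison = paste0(rows$condition, "/", calibrator),
             log2_ratio = rows$log2_ratio,
             stringsAsFactors = FALSE)
}

#' Cross-platform concordance of qPCR and array log2 ratios
#'
#' Ordinary least-squares regression of the array log2 ratios on the qPCR
#' log2 ratios, with the goodness of fit R^2, a t-test of zero slope, and the
#' non-parametric Spearman rank correlation (average ranks on ties).
#'
#' @param qpcr,array paired numeric vectors of log2 ratios, or data.frames
#'   with gene/comparison/log2_ratio columns (merged on gene and comparison).
#' @return list of class `concordance_result`: `slope`, `intercept`,
#'   `r_squared`, `p_slope`, `spearman`, `n`, and the paired data.
#' @export
concordance <- function(qpcr, array) {
  if (is.data.frame(qpcr) && is.data.frame(array)) {
    merged <- merge(qpcr, array, by = c("gene", "comparison"),
                    suffixes = c("_qpcr", "_array"))
    x <- merged$log2_ratio_qpcr
    y <- merged$log2_ratio_array
    pairs <- merged
  } else {
    if (length(qpcr) != length(array))
      stop("qPCR and array ratio vectors must be paired")
    x <- as.numeric(qpcr)
    y <- as.numeric(array)
    pairs <- data.frame(qpcr = x, array = y)
  }
  if (length(x) < 3) stop("need at least 3 ratio pairs")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact agreement is a legal input
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_slope = sm$coefficients[2, 4],
                 spearman = stats::cor(x, y, method = "spearman"),
                 n = length(x),
                 pairs = pairs),
            class = "concordance_result")
}
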