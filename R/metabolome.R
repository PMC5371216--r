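#' Comparisons reported for the rehydration metabolome
#'
#' Fold changes are tabulated for desiccated vs hydrated (DRY/HYD) and for
#' each rehydration time against both baselines (R12/DRY, R24/DRY, R12/HYD,
#' R24/HYD).
#' @export
METAB_COMPARISONS <- data.frame(
  comparison = c("DRY/HYD", "R12/DRY", "R24/DRY", "R12/HYD", "R24/HYD"),
  num = c("DRY", "R12", "R24", "R12", "R24"),
  den = c("HYD", "DRY", "DRY", "HYD", "HYD"),
  stringsAsFactors = FALSE
)

#' Welch's two-sample t-test
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value ([stats::t.test] with `var.equal = FALSE`). Degenerate
#' input where both groups have zero variance is defined as t = 0, p = 1 when
#' the means are equal and p = 0 otherwise.
#'
#' @param a,b numeric vectors with at least two values each (typically
#'   log-transformed abundances).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Per-group replicate values of a metabolite table
#' @keywords internal
metab_group_values <- function(table, metabolite, group) {
  cols <- which(table$design$group == group)
  table$abund[metabolite, cols]
}

#' Welch tests and fold-change ratios for the standard comparison set
#'
#' For every metabolite and every comparison in [METAB_COMPARISONS], runs a
#' Welch t-test on the natural-log-transformed replicate abundances (the
#' choice of log base does not affect t or p) and computes the linear ratio
#' of the raw group means.
#'
#' @param table a `metabolite_table` (see [generate_metabolome()]).
#' @param alpha per-comparison significance level (default 0.05; no
#'   multiple-testing correction is applied to metabolite p-values).
#' @return data.frame of class `metab_welch` with one row per metabolite x
#'   comparison: metabolite, comparison, ratio, t, df, p, significant,
#'   direction (`"up"`, `"down"`, `"none"`).
#' @export
metab_welch_table <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "metabolite_table"))
  mets <- rownames(table$abund)
  rows <- vector("list", length(mets) * nrow(METAB_COMPARISONS))
  ri <- 0L
  for (m in mets) {
    for (ci in seq_len(nrow(METAB_COMPARISONS))) {
      num <- metab_group_values(table, m, METAB_COMPARISONS$num[ci])
      den <- metab_group_values(table, m, METAB_COMPARISONS$den[ci])
      num <- num[is.finite(num)]
      den <- den[is.finite(den)]
      w <- welch_t(log(num), log(den))
      sig <- w$p < alpha
      ratio <- mean(num) / mean(den)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        metabolite = m,
        comparison = METAB_COMPARISONS$comparison[ci],
        ratio = ratio, t = w$t, df = w$df, p = w$p, significant = sig,
        direction = if (!sig) "none" else if (ratio > 1) "up" else "down",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("metab_welch", class(res))
  res
}

#' Significance-masked fold-change table
#'
#' Reshapes the Welch results into a metabolite x comparison ratio table in
#' which a cell is blank (NA) when the corresponding Welch test is not
#' significant -- a blank indicates a non-significant difference, not a
#' missing measurement.
#'
#' @param welch a `metab_welch` table from [metab_welch_table()], or a
#'   `metabolite_table` (tested first).
#' @param alpha significance level used for masking when a raw table is
#'   given.
#' @return list of class `ratio_table`: `ratios` (masked matrix), `unmasked`
#'   (all ratios), `significant`, `direction` (character matrix).
#' @export
ratio_table <- function(welch, alpha = 0.05) {
  if (inherits(welch, "metabolite_table"))
    welch <- metab_welch_table(welch, alpha = alpha)
  mets <- unique(welch$metabolite)
  comps <- METAB_COMPARISONS$comparison
  shape <- function(col, default) {
    m <- matrix(default, length(mets), length(comps),
                dimnames = list(mets, comps))
    m[cbind(welch$metabolite, welch$comparison)] <- welch[[col]]
    m
  }
  ratios <- shape("ratio", NA_real_)
  sig <- shape("significant", NA)
  direction <- shape("direction", NA_character_)
  masked <- ratios
  masked[!sig] <- NA_real_
  structure(list(ratios = masked, unmasked = ratios, significant = sig,
                 direction = direction),
            class = "ratio_table")
}

#' Rehydration trajectory classes
#' @export
TRAJECTORY_CLASSES <- c("increased_further", "remained_elevated",
                        "depleted_further", "remained_depleted",
                        "returned_to_control", "declined_toward_control")

#' Classify a metabolite's rehydration trajectory from significance flags
#'
#' A pure function of the per-comparison direction flags (values `"up"`,
#' `"down"`, `"none"` for the five comparisons DRY/HYD, R12/DRY, R24/DRY,
#' R12/HYD, R24/HYD). The decision table, applied top-down:
#' \enumerate{
#'   \item increased_further: significantly up vs DRY and up vs HYD during
#'     rehydration;
#'   \item remained_elevated: up vs HYD but no significant change vs DRY;
#'   \item depleted_further: down vs DRY and down vs HYD;
#'   \item remained_depleted: down vs HYD but no significant change vs DRY;
#'   \item returned_to_control: a significant DRY/HYD change with no
#'     significant R24/HYD difference;
#'   \item declined_toward_control: everything else.
#' }
#' The chain is total and mutually exclusive over all flag combinations.
#'
#' @param flags named character vector over the five comparisons with values
#'   in `c("up", "down", "none")`.
#' @return one of [TRAJECTORY_CLASSES].
#' @export
classify_trajectory <- function(flags) {
  need <- METAB_COMPARISONS$comparison
  if (!all(need %in% names(flags)))
    stop("flags must be named by the five standard comparisons")
  flags <- flags[need]
  if (!all(flags %in% c("up", "down", "none")))
    stop("flags must be 'up', 'down' or 'none'")
  reh_dry <- flags[c("R12/DRY", "R24/DRY")]
  reh_hyd <- flags[c("R12/HYD", "R24/HYD")]
  if (any(reh_dry == "up") && any(reh_hyd == "up"))
    return("increased_further")
  if (any(reh_hyd == "up") && all(reh_dry == "none"))
    return("remained_elevated")
  if (any(reh_dry == "down") && any(reh_hyd == "down"))
    return("depleted_further")
  if (any(reh_hyd == "down") && all(reh_dry == "none"))
    return("remained_depleted")
  if (flags[["DRY/HYD"]] != "none" && flags[["R24/HYD"]] == "none")
    return("returned_to_control")
  "declined_toward_control"
}

#' Classify every metabolite in a ratio table
#'
#' @param rt a `ratio_table`.
#' @return data.frame with metabolite and trajectory columns.
#' @export
classify_trajectories <- function(rt) {
  stopifnot(inherits(rt, "ratio_table"))
  mets <- rownames(rt$direction)
  data.frame(
    metabolite = mets,
    trajectory = vapply(mets, function(m) classify_trajectory(rt$direction[m, ]),
                        ""),
    stringsAsFactors = FALSE, row.names = NULL)
}
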