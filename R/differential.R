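#' Condition groups for the two analysis series
#'
#' The dehydration treatments are ordered by relative water content and the
#' rehydration treatments by time after rewatering, so the two series are
#' analysed as separate groups: dehydration spans HYD through DRY, and
#' rehydration spans DRY, R12 and R24.
#'
#' @param name `"dehydration"` or `"rehydration"`.
#' @return list of class `condition_group` with `name` and ordered
#'   `conditions`.
#' @export
condition_group <- function(name = c("dehydration", "rehydration")) {
  name <- match.arg(name)
  conditions <- switch(name,
    dehydration = c("HYD", "RWC80", "RWC60", "RWC40", "RWC30", "DRY"),
    rehydration = c("DRY", "R12", "R24"))
  structure(list(name = name, conditions = conditions),
            class = "condition_group")
}

#' One-way fixed-effects ANOVA
#'
#' Classic one-way ANOVA from the between/within sums of squares, with an
#' explicit contract for degenerate input: when every group is constant and
#' all means are equal the statistic is defined as F = 0, p = 1; when the
#' within-group variance is exactly zero but means differ, p = 0.
#'
#' @param groups list of numeric vectors, one per condition; at least two
#'   groups with at least two values each (groups may be ragged after
#'   cleansing).
#' @return list with `F`, `p`, `df` (numerator, denominator), `ms_within`.
#' @export
oneway_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  ni <- lengths(groups)
  if (any(ni < 2)) stop("every group needs at least 2 values")
  k <- length(groups)
  N <- sum(ni)
  means <- vapply(groups, mean, 0)
  grand <- sum(ni * means) / N
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1
  df2 <- N - k
  msw <- ssw / df2
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p = 1, df = c(df1, df2), ms_within = 0))
    return(list(F = Inf, p = 0, df = c(df1, df2), ms_within = 0))
  }
  f <- (ssb / df1) / msw
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), ms_within = msw)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment ([stats::p.adjust] with
#' `method = "BH"`): monotone, clipped at 1.
#'
#' @param pvals numeric vector of p-values.
#' @return adjusted p-values of the same length.
#' @export
bh_fdr <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Tukey-Kramer post-hoc pairwise comparisons
#'
#' Studentised-range pairwise tests on the one-way ANOVA fit. For each
#' condition pair the standard error is
#' `sqrt(MSW / 2 * (1/n_i + 1/n_j))` (the Tukey-Kramer generalisation for
#' unequal group sizes), `q = |diff| / SE`, and the p-value comes from the
#' studentised-range distribution with `k` means and the ANOVA residual
#' degrees of freedom.
#'
#' @param groups named list of numeric vectors, one per condition.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with one row per pair: group1, group2, diff
#'   (mean(group2) - mean(group1)), se, q, p, significant.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  ni <- lengths(groups)
  if (any(ni < 2)) stop("every group needs at least 2 values")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  N <- sum(ni)
  msw <- oneway_anova(groups)$ms_within
  means <- vapply(groups, mean, 0)
  pairs <- utils::combn(k, 2)
  res <- data.frame(
    group1 = names(groups)[pairs[1, ]],
    group2 = names(groups)[pairs[2, ]],
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    stringsAsFactors = FALSE
  )
  res$se <- sqrt(msw / 2 * (1 / ni[pairs[1, ]] + 1 / ni[pairs[2, ]]))
  res$q <- ifelse(res$se > 0, abs(res$diff) / res$se,
                  ifelse(res$diff == 0, 0, Inf))
  res$p <- ifelse(is.infinite(res$q), 0,
                  stats::ptukey(res$q, nmeans = k, df = N - k,
                                lower.tail = FALSE))
  res$p[res$q == 0] <- 1
  res$significant <- res$p < alpha
  rownames(res) <- NULL
  res
}

#' Surviving replicate values per gene and condition
#' @keywords internal
group_values <- function(cleansed, gene, conditions) {
  lapply(stats::setNames(conditions, conditions), function(cn) {
    cols <- which(cleansed$design$condition == cn)
    v <- cleansed$expr[gene, cols]
    v[cleansed$mask[gene, cols]]
  })
}

#' Exclude genes with too few surviving replicates in a condition group
#'
#' A gene is excluded from a condition group when, after cleansing, any
#' condition in the group retains fewer than two replicate values (a single
#' value gives no within-group variance to test against).
#'
#' @param cleansed a `cleansed_dataset` from [cleanse_dataset()].
#' @param group a [condition_group()].
#' @param min_replicates minimum surviving values per condition (default 2).
#' @return list with `retained` and `excluded` gene id vectors.
#' @export
filter_insufficient <- function(cleansed, group, min_replicates = 2L) {
  stopifnot(inherits(cleansed, "cleansed_dataset"))
  counts <- sapply(group$conditions, function(cn) {
    cols <- which(cleansed$design$condition == cn)
    rowSums(cleansed$mask[, cols, drop = FALSE])
  })
  ok <- apply(counts >= min_replicates, 1, all)
  genes <- rownames(cleansed$expr)
  list(retained = genes[ok], excluded = genes[!ok])
}

#' Designate significantly differentially abundant transcripts (SDATs)
#'
#' For each condition group, runs a per-gene one-way ANOVA across the group's
#' conditions on the cleansed replicate values, adjusts the p-values by
#' Benjamini-Hochberg across all genes tested within that group, designates
#' genes with adjusted p below `alpha` as SDATs, and runs a Tukey-Kramer
#' post-hoc test on each SDAT to determine under which pairwise comparison it
#' is differentially abundant. Per-comparison log2 fold changes are the
#' ratios of anti-logged condition means. The two groups are corrected
#' separately; the reported SDAT set is the union.
#'
#' @param cleansed a `cleansed_dataset`.
#' @param groups list of [condition_group()]s (default: dehydration and
#'   rehydration).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return list of class `sdat_results` with one element per group, each a
#'   list of `table` (gene, F, p, p_adj, is_sdat), `tukey` (named list over
#'   SDATs of [tukey_hsd()] tables), `fold_changes` (SDATs x pairwise
#'   comparisons, log2), `excluded` (genes with insufficient values); plus
#'   `sdat_union`.
#' @export
designate_sdats <- function(cleansed,
                            groups = list(condition_group("dehydration"),
                                          condition_group("rehydration")),
                            alpha = 0.05) {
  stopifnot(inherits(cleansed, "cleansed_dataset"))
  out <- list()
  for (grp in groups) {
    flt <- filter_insufficient(cleansed, grp)
    genes <- flt$retained
    stat <- vapply(genes, function(g) {
      a <- oneway_anova(group_values(cleansed, g, grp$conditions))
      c(a$F, a$p)
    }, numeric(2))
    tab <- data.frame(gene = genes, F = stat[1, ], p = stat[2, ],
                      stringsAsFactors = FALSE)
    tab$p_adj <- bh_fdr(tab$p)
    tab$is_sdat <- tab$p_adj < alpha
    rownames(tab) <- NULL

    sdats <- tab$gene[tab$is_sdat]
    tukey <- lapply(stats::setNames(sdats, sdats), function(g) {
      tukey_hsd(group_values(cleansed, g, grp$conditions), alpha = alpha)
    })
    npair <- choose(length(grp$conditions), 2)
    fc <- matrix(NA_real_, length(sdats), npair)
    if (length(sdats) > 0) {
      pair_names <- paste(tukey[[1]]$group2, tukey[[1]]$group1, sep = "/")
      for (i in seq_along(sdats)) {
        gv <- group_values(cleansed, sdats[i], grp$conditions)
        am <- vapply(gv, function(v) mean(2^v), 0)
        tk <- tukey[[i]]
        fc[i, ] <- log2(am[tk$group2] / am[tk$group1])
      }
      dimnames(fc) <- list(sdats, pair_names)
    }
    out[[grp$name]] <- list(table = tab, tukey = tukey, fold_changes = fc,
                            excluded = flt$excluded, group = grp)
  }
  out$sdat_union <- sort(unique(unlist(lapply(
    out[names(out) != "sdat_union"],
    function(r) r$table$gene[r$table$is_sdat]))))
  structure(out, class = "sdat_results")
}
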