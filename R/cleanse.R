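#' Maximum standardised deviation in a group of n values
#'
#' For any real n-tuple, the largest value of `|x_i - mean| / sd` (sample
#' standard deviation, n - 1 denominator) is `(n - 1) / sqrt(n)`, attained
#' when one value sits apart from n - 1 equal values. For triplicates this is
#' `2 / sqrt(3) = 1.1547`, which is why at most one replicate of three can
#' ever lie more than one standard deviation from the triplicate mean.
#'
#' @param n group size, >= 2.
#' @return the bound `(n - 1) / sqrt(n)`.
#' @export
max_abs_z_bound <- function(n) {
  if (any(n < 2)) stop("n must be >= 2")
  (n - 1) / sqrt(n)
}

#' Summary statistics of a replicate triplicate
#'
#' @param values three log2 expression values.
#' @return list with `values`, `mean`, `sd` (sample, n - 1), `cv` (sd/mean;
#'   NA when mean <= 0), and `z` (standardised deviations; zero when sd = 0).
#' @export
triplicate_stats <- function(values) {
  if (length(values) != 3 || any(!is.finite(values)))
    stop("values must be three finite numbers")
  m <- mean(values)
  s <- stats::sd(values)
  cv <- if (m > 0) s / m else NA_real_
  z <- if (s > 0) (values - m) / s else rep(0, 3)
  list(values = values, mean = m, sd = s, cv = cv, z = z)
}

#' Cleanse one triplicate of replicate expression values
#'
#' The replicate-cleansing rule: a triplicate whose coefficient of variation
#' exceeds `cv_scrutiny` is scrutinised. If exactly one replicate lies more
#' than `z_cut` sample standard deviations from the triplicate mean it is
#' dropped as a single outlier, provided its removal moderates the CV
#' (post-removal two-value CV <= `cv_scrutiny`). A scrutinised triplicate
#' with no removable outlier, or one whose removal does not moderate the CV,
#' is dropped entirely when its CV exceeds `cv_hard`, and otherwise kept with
#' a flag. Triplicates with non-positive mean are kept unfiltered with a
#' warning record (the CV is undefined there).
#'
#' @param values three finite log2 expression values.
#' @param cv_scrutiny CV above which a triplicate is scrutinised (default
#'   0.5).
#' @param cv_hard CV above which an unmoderatable triplicate is excluded as a
#'   complete replicate set (default 0.75).
#' @param z_cut standardised-deviation cut for single-outlier designation;
#'   strict inequality (default 1).
#' @return list of class `triplicate_decision`: `action` (`"keep"`,
#'   `"drop_one"`, `"drop_all"`), `drop_index` (NA unless `drop_one`),
#'   `trigger` (`"none"`, `"cv_scrutiny"`, `"hard_cv"`), `flagged` (kept but
#'   scrutinised), `warn` (degenerate mean), and `stats`.
#' @export
cleanse_triplicate <- function(values, cv_scrutiny = 0.5, cv_hard = 0.75,
                               z_cut = 1.0) {
  st <- triplicate_stats(values)
  dec <- function(action, drop_index = NA_integer_, trigger = "none",
                  flagged = FALSE, warn = FALSE) {
    structure(list(action = action, drop_index = drop_index,
                   trigger = trigger, flagged = flagged, warn = warn,
                   stats = st),
              class = "triplicate_decision")
  }
  if (!is.finite(st$cv)) return(dec("keep", warn = TRUE))
  if (st$cv <= cv_scrutiny) return(dec("keep"))

  out <- which(abs(st$z) > z_cut)
  if (length(out) == 1) {
    pair <- st$values[-out]
    pair_m <- mean(pair)
    pair_cv <- if (pair_m > 0) stats::sd(pair) / pair_m else Inf
    if (pair_cv <= cv_scrutiny)
      return(dec("drop_one", drop_index = out, trigger = "cv_scrutiny"))
  }
  if (st$cv > cv_hard) return(dec("drop_all", trigger = "hard_cv"))
  dec("keep", trigger = "cv_scrutiny", flagged = TRUE)
}

#' Cleanse every gene x condition triplicate of an expression dataset
#'
#' Applies [cleanse_triplicate()] to each triplicate, returning the dataset
#' with a keep mask and a full decision log (one row per gene x condition),
#' along with summary counts in the reporting style of the original analysis
#' (fraction of triplicates scrutinised, values excluded as single outliers,
#' complete replicate sets excluded).
#'
#' @param dataset an `expr_dataset` (see [generate_expression()]), or a plain
#'   log2 matrix with columns `<condition>_<replicate>` plus a `design`
#'   argument.
#' @param design design data.frame (sample, condition, replicate); taken from
#'   `dataset` when it is an `expr_dataset`.
#' @inheritParams cleanse_triplicate
#' @return list of class `cleansed_dataset`: `expr`, `design`, `conditions`,
#'   `mask` (logical, TRUE = value retained), `decisions` (gene, condition,
#'   mean, sd, cv, z1..z3, action, drop_index, trigger, flagged, warn), and
#'   `summary` (counts).
#' @export
cleanse_dataset <- function(dataset, design = NULL, cv_scrutiny = 0.5,
                            cv_hard = 0.75, z_cut = 1.0) {
  if (inherits(dataset, "expr_dataset")) {
    expr <- dataset$expr
    design <- dataset$design
  } else {
    expr <- as.matrix(dataset)
    if (is.null(design)) stop("design required for a plain matrix")
  }
  conds <- unique(design$condition)
  genes <- rownames(expr)
  mask <- matrix(TRUE, nrow(expr), ncol(expr), dimnames = dimnames(expr))

  logs <- vector("list", length(conds))
  for (ci in seq_along(conds)) {
    cols <- which(design$condition == conds[ci])
    if (length(cols) != 3)
      stop("cleansing rule is defined for triplicates")
    block <- expr[, cols, drop = FALSE]
    n <- nrow(block)
    entry <- data.frame(gene = genes, condition = conds[ci],
                        mean = NA_real_, sd = NA_real_, cv = NA_real_,
                        z1 = NA_real_, z2 = NA_real_, z3 = NA_real_,
                        action = "keep", drop_index = NA_integer_,
                        trigger = "none", flagged = FALSE, warn = FALSE,
                        stringsAsFactors = FALSE)
    m <- rowMeans(block)
    s <- sqrt(pmax(0, (rowSums(block^2) - 3 * m^2) / 2))
    cv <- ifelse(m > 0, s / m, NA_real_)
    entry$mean <- m
    entry$sd <- s
    entry$cv <- cv
    z <- (block - m) / ifelse(s > 0, s, 1)
    z[s == 0, ] <- 0
    entry[, c("z1", "z2", "z3")] <- z
    entry$warn <- !is.finite(cv)

    needs <- which(is.finite(cv) & cv > cv_scrutiny)
    for (g in needs) {
      d <- cleanse_triplicate(block[g, ], cv_scrutiny, cv_hard, z_cut)
      entry$action[g] <- d$action
      entry$drop_index[g] <- d$drop_index
      entry$trigger[g] <- d$trigger
      entry$flagged[g] <- d$flagged
      if (d$action == "drop_one") {
        mask[g, cols[d$drop_index]] <- FALSE
      } else if (d$action == "drop_all") {
        mask[g, cols] <- FALSE
      }
    }
    logs[[ci]] <- entry
  }
  decisions <- do.call(rbind, logs)
  rownames(decisions) <- NULL

  n_trip <- nrow(decisions)
  summary <- list(
    n_triplicates = n_trip,
    n_scrutinized = sum(decisions$trigger != "none" |
                          decisions$action != "keep"),
    frac_cv_above_scrutiny = mean(decisions$cv > cv_scrutiny, na.rm = TRUE),
    n_single_outliers = sum(decisions$action == "drop_one"),
    n_complete_exclusions = sum(decisions$action == "drop_all"),
    n_values_excluded = sum(!mask),
    mean_cv_retained = mean(decisions$cv[decisions$action == "keep"],
                            na.rm = TRUE)
  )
  structure(list(expr = expr, design = design, conditions = conds,
                 mask = mask, decisions = decisions, summary = summary),
            class = "cleansed_dataset")
}
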