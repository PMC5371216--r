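#' Experimental design constants
#'
#' The hydration series comprises eight conditions sampled in biological
#' triplicate: full hydration (`HYD`, ~96% relative water content), four
#' dehydration stages (`RWC80`, `RWC60`, `RWC40`, `RWC30`), the desiccated
#' state (`DRY`, ~11% RWC), and two rehydration time points (`R12`, `R24`,
#' 12 h and 24 h after rewatering). The metabolome series omits `RWC80` and
#' uses six replicates per group.
#'
#' @format Character vectors of condition labels.
#' @name design-constants
NULL

#' @rdname design-constants
#' @export
EXPR_CONDITIONS <- c("HYD", "RWC80", "RWC60", "RWC40", "RWC30", "DRY",
                     "R12", "R24")

#' @rdname design-constants
#' @export
METAB_GROUPS <- c("HYD", "RWC60", "RWC40", "RWC30", "DRY", "R12", "R24")

#' @rdname design-constants
#' @export
EXPR_REPLICATES <- 3L

#' @rdname design-constants
#' @export
METAB_REPLICATES <- 6L

#' Archetype mean profiles
#'
#' Fixed log2 deviations from each gene's baseline across the eight
#' conditions, one row per profile archetype. The shapes emulate the
#' predominant expression clusters seen during a dehydration-rehydration
#' cycle in a resurrection grass:
#' \describe{
#'   \item{constant}{null profile, no change anywhere.}
#'   \item{rise_plateau}{abundance rises between 80 and 60% RWC and plateaus
#'     from 40% RWC through desiccation (the classic LEA-dominated pattern).}
#'   \item{peak_30}{abundance peaks sharply at 30% RWC.}
#'   \item{decline}{little change down to 60% RWC, then a steep decline to
#'     the dry state (photosynthesis-associated transcripts).}
#'   \item{dip_rise}{an early rise held steady until 40% RWC, a dip at
#'     30% RWC, then renewed accumulation in the dry state.}
#'   \item{rise_crash}{a steady rise to 40% RWC held to 30% RWC followed by a
#'     crash on desiccation.}
#' }
#' The exact values are package constants chosen so that profiles of
#' different archetypes are well separated under the average-pairwise-Pearson
#' cluster criterion (between-archetype r <= 0.61 over the six dehydration
#' conditions).
#'
#' @format A 6 x 8 numeric matrix; rows are archetypes, columns conditions.
#' @export
ARCHETYPE_PROFILES <- local({
  m <- rbind(
    constant     = c(0,  0,     0,     0,     0,     0,    0,     0),
    rise_plateau = c(0,  0.4,   1.6,   2.0,   2.0,   2.0,  1.0,   0.5),
    peak_30      = c(0,  0.05,  0.15,  0.7,   2.2,   0.5,  0.25,  0.1),
    decline      = c(0, -0.15, -0.3,  -1.3,  -2.2,  -2.4, -1.4,  -0.7),
    dip_rise     = c(0,  0.9,   0.9,   0.9,   0.25,  1.4,  1.0,   0.8),
    rise_crash   = c(0,  1.5,   1.7,   1.7,   1.4,   0.1,  0.05,  0.0)
  )
  colnames(m) <- c("HYD", "RWC80", "RWC60", "RWC40", "RWC30", "DRY",
                   "R12", "R24")
  m
})

#' Metabolite trajectory mean profiles
#'
#' Unit-effect log2 deviations from baseline across the seven metabolome
#' groups. Scaled by `metab_effect_log2` in the generator. Patterns cover the
#' rehydration trajectories the analysis classifies: accumulation during
#' dehydration that increases further, remains elevated, or returns to
#' control on rehydration, plus the depleted mirror images.
#'
#' @format A 7 x 7 numeric matrix; rows are patterns, columns groups.
#' @export
METAB_PATTERNS <- local({
  m <- rbind(
    null        = c(0, 0,    0,    0,    0,    0,    0),
    up_further  = c(0, 0.3,  0.6,  0.8,  1.0,  1.8,  2.4),
    up_stay     = c(0, 0.3,  0.6,  0.8,  1.0,  1.0,  1.0),
    up_return   = c(0, 0.3,  0.6,  0.8,  1.0,  0.4,  0.05),
    down_further= c(0, -0.3, -0.6, -0.8, -1.0, -1.8, -2.4),
    down_stay   = c(0, -0.3, -0.6, -0.8, -1.0, -1.0, -1.0),
    down_return = c(0, -0.3, -0.6, -0.8, -1.0, -0.4, -0.05)
  )
  colnames(m) <- c("HYD", "RWC60", "RWC40", "RWC30", "DRY", "R12", "R24")
  m
})

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators with validation.
#' The defaults are the study conditions the package emulates: 8 conditions x
#' 3 replicates for expression, 7 groups x 6 replicates for the metabolome,
#' log2-scale Gaussian replicate noise, and a 10% rate of gross
#' single-replicate outliers (mirroring the fraction of triplicates the
#' original cleansing step scrutinised).
#'
#' @param n_genes number of genes to simulate.
#' @param archetype_weights named proportions over the rows of
#'   [ARCHETYPE_PROFILES]; must sum to 1.
#' @param noise_sd replicate noise standard deviation, log2 units.
#' @param outlier_rate probability that a gene x condition triplicate
#'   contains one planted outlier.
#' @param outlier_shift magnitude of the planted additive shift, log2 units;
#'   sign is random. The default (13) places shifted triplicates inside the
#'   CV > 0.5 trigger window of the cleansing rule for the baseline scale
#'   used here.
#' @param baseline_range range of the uniform draw for per-gene baseline
#'   log2 abundance.
#' @param n_metabolites number of metabolites to simulate.
#' @param metab_effect_log2 scale applied to [METAB_PATTERNS] (1 = planted
#'   two-fold peak effects).
#' @param metab_weights named proportions over the rows of [METAB_PATTERNS].
#' @param metab_noise_sd log2-scale noise for metabolite replicates
#'   (abundances are lognormal).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       archetype_weights = c(constant = 0.5,
                                             rise_plateau = 0.1,
                                             peak_30 = 0.1,
                                             decline = 0.1,
                                             dip_rise = 0.1,
                                             rise_crash = 0.1),
                       noise_sd = 0.2,
                       outlier_rate = 0.1,
                       outlier_shift = 13,
                       baseline_range = c(7, 8),
                       n_metabolites = 200L,
                       metab_effect_log2 = 1,
                       metab_weights = c(null = 0.4,
                                         up_further = 0.1,
                                         up_stay = 0.1,
                                         up_return = 0.1,
                                         down_further = 0.1,
                                         down_stay = 0.1,
                                         down_return = 0.1),
                       metab_noise_sd = 0.25,
                       seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (n_metabolites < 1) stop("n_metabolites must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (metab_noise_sd < 0) stop("metab_noise_sd must be >= 0")
  if (outlier_rate < 0 || outlier_rate > 1)
    stop("outlier_rate must lie in [0, 1]")
  if (!all(names(archetype_weights) %in% rownames(ARCHETYPE_PROFILES)))
    stop("unknown archetype in archetype_weights")
  if (abs(sum(archetype_weights) - 1) > 1e-8)
    stop("archetype_weights must sum to 1")
  if (!all(names(metab_weights) %in% rownames(METAB_PATTERNS)))
    stop("unknown pattern in metab_weights")
  if (abs(sum(metab_weights) - 1) > 1e-8)
    stop("metab_weights must sum to 1")
  structure(list(n_genes = as.integer(n_genes),
                 archetype_weights = archetype_weights,
                 noise_sd = noise_sd,
                 outlier_rate = outlier_rate,
                 outlier_shift = outlier_shift,
                 baseline_range = baseline_range,
                 n_metabolites = as.integer(n_metabolites),
                 metab_effect_log2 = metab_effect_log2,
                 metab_weights = metab_weights,
                 metab_noise_sd = metab_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Largest-remainder integer allocation of n items to weighted labels
#' @keywords internal
alloc_labels <- function(weights, n) {
  exact <- weights * n
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(-(exact - counts), names(weights))[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  rep(names(weights), counts)
}

#' Generate a synthetic expression dataset with planted ground truth
#'
#' Draws per-gene baselines, assigns profile archetypes, adds Gaussian
#' replicate noise on the log2 scale, and plants single-replicate outliers
#' (additive shifts of random sign) in a fraction of the gene x condition
#' triplicates. No triplicate receives more than one planted outlier.
#'
#' @param config a [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{dataset}{class `expr_dataset`: `expr` (genes x 24 log2 matrix,
#'       columns `<condition>_<replicate>`), `design` (sample, condition,
#'       replicate), `conditions`.}
#'     \item{truth}{class `ground_truth`: per-gene `archetype`,
#'       `is_differential`, and `outliers` (gene, condition, replicate,
#'       shift).}
#'   }
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("gene_%05d", seq_len(n))
  conds <- EXPR_CONDITIONS
  reps <- EXPR_REPLICATES

  # deterministic largest-remainder allocation: the planted composition
  # matches the requested proportions exactly, then labels are shuffled
  archetypes <- sample(alloc_labels(config$archetype_weights, n))
  names(archetypes) <- genes
  baseline <- stats::runif(n, config$baseline_range[1],
                           config$baseline_range[2])

  design <- data.frame(
    sample = paste(rep(conds, each = reps), rep(seq_len(reps), length(conds)),
                   sep = "_"),
    condition = rep(conds, each = reps),
    replicate = rep(seq_len(reps), length(conds)),
    stringsAsFactors = FALSE
  )

  mu <- baseline + ARCHETYPE_PROFILES[archetypes, conds, drop = FALSE]
  expr <- mu[, rep(seq_along(conds), each = reps)] +
    matrix(stats::rnorm(n * nrow(design), sd = config$noise_sd),
           nrow = n)
  dimnames(expr) <- list(genes, design$sample)

  # plant at most one outlier per triplicate
  hit <- matrix(stats::runif(n * length(conds)) < config$outlier_rate,
                nrow = n, dimnames = list(genes, conds))
  idx <- which(hit, arr.ind = TRUE)
  outliers <- data.frame(gene = character(0), condition = character(0),
                         replicate = integer(0), shift = numeric(0),
                         stringsAsFactors = FALSE)
  if (nrow(idx) > 0) {
    rep_pick <- sample.int(reps, nrow(idx), replace = TRUE)
    sign_pick <- sample(c(-1, 1), nrow(idx), replace = TRUE)
    shift <- sign_pick * config$outlier_shift
    col_pick <- (idx[, 2] - 1L) * reps + rep_pick
    expr[cbind(idx[, 1], col_pick)] <- expr[cbind(idx[, 1], col_pick)] + shift
    outliers <- data.frame(gene = genes[idx[, 1]],
                           condition = conds[idx[, 2]],
                           replicate = rep_pick,
                           shift = shift,
                           stringsAsFactors = FALSE)
  }

  dataset <- structure(list(expr = expr, design = design, conditions = conds),
                       class = "expr_dataset")
  truth <- structure(list(archetype = archetypes,
                          is_differential = archetypes != "constant",
                          outliers = outliers),
                     class = "ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Generate a synthetic metabolite table with planted ground truth
#'
#' Metabolite abundances are lognormal: a per-metabolite baseline and a
#' planted trajectory pattern (log2 scale) plus Gaussian log-scale noise,
#' exponentiated so that all abundances are strictly positive.
#'
#' @param config a [sim_config()].
#' @return A list with `table` (class `metabolite_table`: `abund`,
#'   metabolites x 42 positive matrix with columns `<group>_<replicate>`;
#'   `groups`; `design`) and `truth` (per-metabolite `pattern`,
#'   `is_differential`, and the planted `group_means_log2` matrix).
#' @export
generate_metabolome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_metabolites
  mets <- sprintf("met_%04d", seq_len(n))
  groups <- METAB_GROUPS
  reps <- METAB_REPLICATES

  patterns <- sample(alloc_labels(config$metab_weights, n))
  names(patterns) <- mets
  baseline <- stats::runif(n, 3, 10)
  mu <- baseline + config$metab_effect_log2 *
    METAB_PATTERNS[patterns, groups, drop = FALSE]
  rownames(mu) <- mets

  design <- data.frame(
    sample = paste(rep(groups, each = reps),
                   rep(seq_len(reps), length(groups)), sep = "_"),
    group = rep(groups, each = reps),
    replicate = rep(seq_len(reps), length(groups)),
    stringsAsFactors = FALSE
  )
  log2_abund <- mu[, rep(seq_along(groups), each = reps)] +
    matrix(stats::rnorm(n * nrow(design), sd = config$metab_noise_sd),
           nrow = n)
  abund <- 2^log2_abund
  dimnames(abund) <- list(mets, design$sample)

  table <- structure(list(abund = abund, groups = groups, design = design),
                     class = "metabolite_table")
  truth <- structure(list(pattern = patterns,
                          is_differential = patterns != "null",
                          group_means_log2 = mu),
                     class = "ground_truth")
  list(table = table, truth = truth)
}

#' Generate paired qPCR Ct and array log2-ratio tables
#'
#' Emulates the cross-platform validation experiment: `n_genes` target genes
#' plus one stable reference gene are "measured" in triplicate over the six
#' dehydration conditions; array log2 ratios for the five comparisons vs HYD
#' are generated so that the regression of array on qPCR ratios attains
#' `target_r2` in expectation (the array values equal the realised qPCR
#' ratios plus Gaussian noise with variance `var(q) * (1 - R2) / R2`; with
#' `target_r2 = 1` the two vectors are identical). The achieved R2 of a
#' single draw fluctuates around the target; over many seeds the mean is
#' within about 0.05.
#'
#' @param n_genes number of target genes (default 10).
#' @param target_r2 intended squared correlation between qPCR and array
#'   log2 ratios.
#' @param seed integer seed.
#' @param ct_noise_sd replicate-level Ct noise (cycles).
#' @param ratio_sd spread of the true per-gene, per-condition log2 ratios.
#' @return A list with `ct` (gene, condition, replicate, Ct, is_reference),
#'   `array_ratios` (gene, comparison, log2_ratio), `reference_gene`, and
#'   `true_log2_ratio`.
#' @export
generate_qpcr <- function(n_genes = 10L, target_r2 = 0.843, seed = 1L,
                          ct_noise_sd = 0.05, ratio_sd = 2) {
  if (target_r2 <= 0 || target_r2 > 1) stop("target_r2 must lie in (0, 1]")
  set.seed(seed)
  genes <- sprintf("qgene_%02d", seq_len(n_genes))
  conds <- c("HYD", "RWC80", "RWC60", "RWC40", "RWC30", "DRY")
  reps <- 3L
  ref <- "REF"

  true_ratio <- matrix(stats::rnorm(n_genes * (length(conds) - 1L),
                                    sd = ratio_sd),
                       nrow = n_genes,
                       dimnames = list(genes, conds[-1]))

  grid <- expand.grid(gene = c(genes, ref), condition = conds,
                      replicate = seq_len(reps), stringsAsFactors = FALSE)
  ct0 <- stats::setNames(stats::runif(n_genes, 18, 26), genes)
  delta <- cbind(HYD = 0, true_ratio)
  ct <- rep(15, nrow(grid))
  tgt <- grid$gene != ref
  ct[tgt] <- ct0[grid$gene[tgt]] -
    delta[cbind(grid$gene[tgt], grid$condition[tgt])]
  ct <- ct + stats::rnorm(nrow(grid), sd = ct_noise_sd)
  ct_table <- data.frame(grid, Ct = ct, is_reference = grid$gene == ref,
                         stringsAsFactors = FALSE)

  # realised qPCR ratios from the Ct table itself, so that target_r2 = 1
  # yields an exact R2 of 1 downstream
  q <- qpcr_log2_ratios(ct_table, reference_gene = ref, calibrator = "HYD")
  qv <- q$log2_ratio
  noise_var <- stats::var(qv) * (1 - target_r2) / target_r2
  array_ratio <- qv + stats::rnorm(length(qv), sd = sqrt(noise_var))
  array_ratios <- data.frame(gene = q$gene,
                             comparison = q$comparison,
                             log2_ratio = array_ratio,
                             stringsAsFactors = FALSE)

  list(ct = ct_table, array_ratios = array_ratios, reference_gene = ref,
       true_log2_ratio = true_ratio)
}

#' Generate a calibration standards table
#'
#' Linear peak-area-ratio response to concentration with additive Gaussian
#' noise, emitted in the layout of an LC-MS standards file. The default
#' levels are the seven calibration standards used for abscisic acid
#' quantification (0.5-50 ng/ml).
#'
#' @param levels standard concentrations, ng/ml.
#' @param slope,intercept linear response parameters (area ratio per ng/ml).
#' @param noise_sd additive noise on the area ratio.
#' @param endogenous_ratio constant area-ratio contribution of endogenous
#'   analyte present in the spiked control matrix.
#' @param is_area internal-standard peak area (arbitrary units).
#' @param seed integer seed.
#' @return data.frame with columns conc_ng_ml, analyte_area, is_area.
#' @export
generate_calibration <- function(levels = c(0.5, 1, 2, 5, 10, 25, 50),
                                 slope = 0.2, intercept = 0.01,
                                 noise_sd = 0, endogenous_ratio = 0,
                                 is_area = 1e5, seed = 1L) {
  if (length(levels) < 3) stop("need at least 3 standard levels")
  set.seed(seed)
  ratio <- intercept + slope * levels + endogenous_ratio +
    stats::rnorm(length(levels), sd = noise_sd)
  data.frame(conc_ng_ml = levels,
             analyte_area = ratio * is_area,
             is_area = rep(is_area, length(levels)))
}

#' Relative water content
#'
#' `RWC = (Fwt - Dwt) / (FTwt - Dwt)`: the fresh weight of a sample relative
#' to its full-turgor weight, both in excess of its dry weight.
#'
#' @param Fwt fresh sample weight (g).
#' @param FTwt full-turgor weight after overnight submersion (g).
#' @param Dwt dry weight after drying to equilibrium (g).
#' @return RWC as a fraction; 1 at full turgor, 0 at dry weight. Vectorised.
#' @export
rwc <- function(Fwt, FTwt, Dwt) {
  if (any(FTwt <= Dwt)) stop("FTwt must exceed Dwt")
  (Fwt - Dwt) / (FTwt - Dwt)
}
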