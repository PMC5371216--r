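#' Significance-masked fold-change table for SDATs
#'
#' Log2 fold changes in the figure-legend convention: during dehydration,
#' each dehydrated stage (80, 60, 40, 30% RWC and DRY) against the hydrated
#' state; during rehydration, R12 and R24 against both the dry state and the
#' hydrated state. Fold change is computed on anti-logged means of the
#' cleansed replicate values (a ratio of arithmetic means on the linear
#' scale), and a cell is masked when the corresponding Tukey pair is not
#' significant for that gene.
#'
#' @param cleansed a `cleansed_dataset`.
#' @param sdats an `sdat_results` object from [designate_sdats()].
#' @param linear_scale compute means on the anti-logged (linear) scale
#'   (default TRUE); otherwise arithmetic means of the log2 values are
#'   differenced (a geometric-mean ratio).
#' @return list of class `fold_change_table`: `values` (genes x comparisons,
#'   log2), `mask` (TRUE where the Tukey pair is significant), `masked`
#'   (values with non-significant cells set NA), `comparisons`.
#' @export
fold_changes <- function(cleansed, sdats, linear_scale = TRUE) {
  stopifnot(inherits(cleansed, "cleansed_dataset"),
            inherits(sdats, "sdat_results"))
  comps <- data.frame(
    comparison = c("RWC80/HYD", "RWC60/HYD", "RWC40/HYD", "RWC30/HYD",
                   "DRY/HYD", "R12/DRY", "R24/DRY", "R12/HYD", "R24/HYD"),
    num = c("RWC80", "RWC60", "RWC40", "RWC30", "DRY", "R12", "R24", "R12",
            "R24"),
    den = c("HYD", "HYD", "HYD", "HYD", "HYD", "DRY", "DRY", "HYD", "HYD"),
    group = c(rep("dehydration", 5), rep("rehydration", 2), NA, NA),
    stringsAsFactors = FALSE
  )
  genes <- sdats$sdat_union
  values <- matrix(NA_real_, length(genes), nrow(comps),
                   dimnames = list(genes, comps$comparison))
  mask <- matrix(FALSE, length(genes), nrow(comps),
                 dimnames = list(genes, comps$comparison))

  cond_mean <- function(gene, cn) {
    cols <- which(cleansed$design$condition == cn)
    v <- cleansed$expr[gene, cols]
    v <- v[cleansed$mask[gene, cols]]
    if (length(v) == 0) return(NA_real_)
    if (linear_scale) log2(mean(2^v)) else mean(v)
  }
  tukey_sig <- function(gene, num, den) {
    for (grp in c("dehydration", "rehydration")) {
      tk <- sdats[[grp]]$tukey[[gene]]
      if (is.null(tk)) next
      hit <- (tk$group1 == den & tk$group2 == num) |
             (tk$group1 == num & tk$group2 == den)
      if (any(hit)) return(any(tk$significant[hit]))
    }
    FALSE
  }
  for (g in genes) {
    for (i in seq_len(nrow(comps))) {
      mn <- cond_mean(g, comps$num[i])
      md <- cond_mean(g, comps$den[i])
      values[g, i] <- mn - md
      mask[g, i] <- tukey_sig(g, comps$num[i], comps$den[i])
    }
  }
  masked <- values
  masked[!mask] <- NA_real_
  structure(list(values = values, mask = mask, masked = masked,
                 comparisons = comps$comparison),
            class = "fold_change_table")
}

#' Top-n genes by fold change in one comparison
#'
#' @param fc a `fold_change_table`.
#' @param comparison one of `fc$comparisons`.
#' @param n list length (default 50); the full ranking is returned when the
#'   table is smaller.
#' @param direction `"up"` for the greatest positive fold changes, `"down"`
#'   for the most negative.
#' @param masked rank only cells whose Tukey pair is significant (default
#'   TRUE).
#' @return data.frame gene, log2_fc, rank; ties broken by gene id.
#' @export
top_n <- function(fc, comparison, n = 50L, direction = c("up", "down"),
                  masked = TRUE) {
  stopifnot(inherits(fc, "fold_change_table"))
  direction <- match.arg(direction)
  if (!comparison %in% fc$comparisons) stop("unknown comparison")
  v <- if (masked) fc$masked[, comparison] else fc$values[, comparison]
  v <- v[!is.na(v)]
  ord <- order(if (direction == "up") -v else v, names(v))
  sel <- ord[seq_len(min(n, length(v)))]
  data.frame(gene = names(v)[sel], log2_fc = unname(v[sel]),
             rank = seq_along(sel), stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_checked <- function(path, what) {
  if (!file.exists(path))
    stop("cannot open ", what, " input file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read an expression matrix and design table from TSV files
#'
#' @param expr_path TSV with a `gene` column and one column per sample named
#'   `<condition>_<replicate>`.
#' @param design_path TSV with columns sample, condition, replicate.
#' @return an `expr_dataset`.
#' @export
read_expression_tsv <- function(expr_path, design_path) {
  et <- read_tsv_checked(expr_path, "expression")
  design <- read_tsv_checked(design_path, "design")
  expr <- as.matrix(et[, design$sample, drop = FALSE])
  rownames(expr) <- et$gene
  structure(list(expr = expr, design = design,
                 conditions = unique(design$condition)),
            class = "expr_dataset")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/read -> cleanse -> differential -> cluster ->
#' fold changes -> metabolome -> concordance -> ABA quantification ->
#' enrichment, writing all artifacts as TSV files plus a structured run log
#' of the counts at each stage. Deterministic given the configuration and
#' seed: a re-run writes byte-identical files.
#'
#' @param config either a list or a path to a YAML file. Recognised fields:
#'   simulation parameters (any argument of [sim_config()]), `expr` +
#'   `design` (TSV paths, replacing the simulated expression data), `metab`
#'   (TSV path), `gmt` (gene-set file; default: archetype sets from the
#'   simulation ground truth), thresholds `fdr` (0.05), `cv_scrutiny` (0.5),
#'   `cv_hard` (0.75), `z_cut` (1), `cluster_r` (0.85), and `seed`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with every intermediate result and the output
#'   paths.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("cannot open config file: ", config)
    config <- yaml::read_yaml(config)
  }
  get_opt <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  fdr <- get_opt("fdr", 0.05)
  cv_scrutiny <- get_opt("cv_scrutiny", 0.5)
  cv_hard <- get_opt("cv_hard", 0.75)
  z_cut <- get_opt("z_cut", 1.0)
  cluster_r <- get_opt("cluster_r", 0.85)

  sim_args <- config[intersect(names(config), names(formals(sim_config)))]
  cfg <- do.call(sim_config, sim_args)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  note("desiccatome pipeline run, seed ", cfg$seed)

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  if (!is.null(config[["expr"]])) {
    dataset <- read_expression_tsv(config[["expr"]],
                                   get_opt("design", stop("design TSV required with expr")))
    note("expression read from ", config[["expr"]], ": ", nrow(dataset$expr),
         " genes x ", ncol(dataset$expr), " samples")
  } else {
    sim <- generate_expression(cfg)
    dataset <- sim$dataset
    truth <- sim$truth
    note("simulated expression: ", nrow(dataset$expr), " genes x ",
         ncol(dataset$expr), " samples; ", nrow(truth$outliers),
         " planted outliers")
  }

  if (!is.null(config[["metab"]])) {
    mt <- read_tsv_checked(config[["metab"]], "metabolite")
    abund <- as.matrix(mt[, -1])
    rownames(abund) <- mt[[1]]
    grp <- sub("_[0-9]+$", "", colnames(abund))
    metab <- structure(list(abund = abund, groups = unique(grp),
                            design = data.frame(sample = colnames(abund),
                                                group = grp,
                                                replicate = as.integer(
                                                  sub("^.*_", "", colnames(abund))),
                                                stringsAsFactors = FALSE)),
                       class = "metabolite_table")
    metab_truth <- NULL
  } else {
    msim <- generate_metabolome(cfg)
    metab <- msim$table
    metab_truth <- msim$truth
  }
  note("metabolites: ", nrow(metab$abund))

  # --- expression pipeline ------------------------------------------------
  cleansed <- cleanse_dataset(dataset, cv_scrutiny = cv_scrutiny,
                              cv_hard = cv_hard, z_cut = z_cut)
  s <- cleansed$summary
  note("cleansing: ", s$n_triplicates, " triplicates; ",
       s$n_scrutinized, " scrutinized (CV > ", cv_scrutiny, "); ",
       s$n_single_outliers, " single outliers excluded; ",
       s$n_complete_exclusions, " complete replicate sets excluded; ",
       s$n_values_excluded, " values excluded in total")

  sdats <- designate_sdats(cleansed, alpha = fdr)
  for (grp in c("dehydration", "rehydration")) {
    r <- sdats[[grp]]
    note(grp, ": ", sum(r$table$is_sdat), " SDATs of ", nrow(r$table),
         " genes tested (BH-adjusted p < ", fdr, "); ",
         length(r$excluded), " genes excluded for insufficient values")
  }
  note("SDAT union: ", length(sdats$sdat_union))

  dehyd <- condition_group("dehydration")
  sd_genes <- sdats$dehydration$table$gene[sdats$dehydration$table$is_sdat]
  clusters <- NULL
  if (length(sd_genes) > 0) {
    prof <- condition_profiles(cleansed, dehyd, genes = sd_genes)
    clusters <- threshold_cluster(prof, r_min = cluster_r)
    cs <- cluster_summary(clusters)
    note("dehydration clustering: ", cs$n_clusters, " clusters; ",
         cs$n_clusters_ge_k, " with >= ", cs$k, " SDATs covering ",
         round(100 * cs$frac_in_large, 1), "% of clustered SDATs")
    note("rehydration series has 3 conditions only; its clustering is ",
         "reported as low-confidence and omitted from cluster outputs")
  }

  fc <- fold_changes(cleansed, sdats)

  # --- metabolome ---------------------------------------------------------
  welch <- metab_welch_table(metab, alpha = fdr)
  rt <- ratio_table(welch)
  traj <- classify_trajectories(rt)
  note("metabolome: ", sum(apply(rt$significant, 1, any)),
       " of ", nrow(rt$ratios),
       " metabolites significant in at least one comparison")

  # --- concordance --------------------------------------------------------
  qp <- generate_qpcr(seed = cfg$seed)
  qratios <- qpcr_log2_ratios(qp$ct, reference_gene = qp$reference_gene)
  conc <- concordance(qratios, qp$array_ratios)
  note("qPCR concordance: R^2 = ", round(conc$r_squared, 3),
       ", Spearman rho = ", round(conc$spearman, 3), " over ", conc$n,
       " ratio pairs")

  # --- ABA ----------------------------------------------------------------
  standards <- generate_calibration(seed = cfg$seed, noise_sd = 0.002)
  cal <- fit_calibration(standards)
  aba_samples <- quantify_aba(cal, predict(cal, c(0.5, 1.5, 2.5)))
  note("ABA calibration: slope = ", signif(cal$slope, 4), ", R^2 = ",
       signif(cal$r_squared, 6))

  # --- enrichment ---------------------------------------------------------
  universe <- rownames(dataset$expr)
  if (!is.null(config[["gmt"]])) {
    terms <- read_gmt(config[["gmt"]])
  } else if (!is.null(truth)) {
    terms <- split(names(truth$archetype), truth$archetype)
  } else {
    terms <- NULL
  }
  enr <- NULL
  if (!is.null(terms) && length(sdats$sdat_union) > 0) {
    enr <- hypergeom_enrich(sdats$sdat_union, terms, universe, alpha = fdr)
    note("enrichment: ", sum(enr$enriched), " of ", nrow(enr),
         " terms enriched")
  }

  # --- outputs ------------------------------------------------------------
  paths <- list()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    paths[[name]] <<- p
  }
  for (grp in c("dehydration", "rehydration"))
    emit(sdats[[grp]]$table, paste0("sdats_", grp, ".tsv"))
  if (!is.null(clusters)) {
    emit(data.frame(gene = names(clusters$cluster),
                    cluster_id = unname(clusters$cluster)), "clusters.tsv")
  }
  emit(data.frame(gene = rownames(fc$masked), fc$masked,
                  check.names = FALSE), "foldchanges.tsv")
  emit(welch, "metabolome.tsv")
  emit(traj, "trajectories.tsv")
  emit(conc$pairs, "concordance.tsv")
  emit(aba_samples, "aba.tsv")
  if (!is.null(enr)) emit(enr, "enrichment.tsv")
  emit(cleansed$decisions, "cleansing_log.tsv")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  paths[["run_log.txt"]] <- file.path(out_dir, "run_log.txt")

  invisible(list(config = cfg, dataset = dataset, truth = truth,
                 cleansed = cleansed, sdats = sdats, clusters = clusters,
                 fold_changes = fc, metabolome = list(table = metab,
                                                      truth = metab_truth,
                                                      welch = welch,
                                                      ratios = rt,
                                                      trajectories = traj),
                 concordance = conc, calibration = cal, enrichment = enr,
                 log = log_lines, paths = paths))
}

#' Write the simulated inputs of a configuration to TSV files
#'
#' Emits the expression matrix, design, metabolite, Ct, calibration-standard
#' and ground-truth tables for a configuration, so the pipeline can be run
#' from files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return invisibly, the written paths.
#' @export
write_simulation <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_expression(config)
  msim <- generate_metabolome(config)
  qp <- generate_qpcr(seed = config$seed)
  std <- generate_calibration(seed = config$seed)
  p <- list(
    expression = file.path(out_dir, "expression.tsv"),
    design = file.path(out_dir, "design.tsv"),
    metabolites = file.path(out_dir, "metabolites.tsv"),
    ct = file.path(out_dir, "qpcr_ct.tsv"),
    standards = file.path(out_dir, "standards.tsv"),
    truth = file.path(out_dir, "ground_truth.tsv")
  )
  write_tsv(data.frame(gene = rownames(sim$dataset$expr), sim$dataset$expr,
                       check.names = FALSE), p$expression)
  write_tsv(sim$dataset$design, p$design)
  write_tsv(data.frame(metabolite = rownames(msim$table$abund),
                       msim$table$abund, check.names = FALSE),
            p$metabolites)
  write_tsv(qp$ct, p$ct)
  write_tsv(std, p$standards)
  write_tsv(data.frame(gene = names(sim$truth$archetype),
                       archetype = unname(sim$truth$archetype),
                       is_differential = unname(sim$truth$is_differential)),
            p$truth)
  invisible(p)
}
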