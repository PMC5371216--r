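test_that("one-way ANOVA matches hand computation and base R", {
  # identical groups: no between-group variance
  a <- oneway_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)

  # hand computation: SSB = 13.5 on 1 df, MSW = 1 on 4 df
  b <- oneway_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(b$F, 13.5)
  expect_equal(b$df, c(1, 4))
  ref <- oneway.test(y ~ g, data = data.frame(y = 1:6, g = rep(1:2, each = 3)),
                     var.equal = TRUE)
  expect_equal(b$F, unname(ref$statistic))
  expect_equal(b$p, ref$p.value)

  # degenerate: all groups constant and equal
  d <- oneway_anova(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(d$F, 0)
  expect_equal(d$p, 1)
  # zero within-group variance, different means
  d2 <- oneway_anova(list(c(2, 2), c(5, 5)))
  expect_equal(d2$p, 0)

  expect_error(oneway_anova(list(1:3)), "2 groups")
  expect_error(oneway_anova(list(1:3, 5)), "2 values")
})

test_that("ANOVA p agrees with a permutation oracle and base R on ragged groups", {
  set.seed(77)
  groups <- list(rnorm(3, 0), rnorm(2, 0.5), rnorm(3, 2), rnorm(3, 0.2))
  a <- oneway_anova(groups)
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(seq_along(groups), lengths(groups))))
  ref <- oneway.test(y ~ g, df, var.equal = TRUE)
  expect_equal(a$F, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(a$p, ref$p.value, tolerance = 1e-12)
  pp <- perm_anova_p(groups, n_perm = 4000)
  mc_se <- sqrt(pp * (1 - pp) / 4000)
  expect_lt(abs(a$p - pp), 2 * mc_se + 0.005)
})

test_that("BH adjustment is the step-up procedure", {
  # hand-stepped: (0.01, 0.02, 0.03, 0.04) all adjust to 0.04
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone
  expect_true(all(adj <= 1) && all(adj >= p))
})

test_that("Tukey-Kramer pairwise tests match TukeyHSD", {
  set.seed(5)
  groups <- list(A = rnorm(3, 0), B = rnorm(3, 1.5), C = rnorm(3, 1.6))
  tk <- tukey_hsd(groups)
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(names(groups), lengths(groups))))
  ref <- TukeyHSD(aov(y ~ g, df))$g
  expect_equal(tk$diff, unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(tk$p, unname(ref[, "p adj"]), tolerance = 1e-8)

  # identical groups: nothing significant
  same <- list(A = c(1, 2, 3), B = c(1, 2, 3), C = c(1, 2, 3))
  expect_false(any(tukey_hsd(same)$significant))
})

test_that("Tukey-Kramer uses the closed-form unequal-n standard error", {
  set.seed(8)
  groups <- list(A = rnorm(3), B = rnorm(2, 1), C = rnorm(3, 2))
  tk <- tukey_hsd(groups)
  msw <- oneway_anova(groups)$ms_within
  ab <- tk[tk$group1 == "A" & tk$group2 == "B", ]
  expect_equal(ab$se, sqrt(msw / 2 * (1 / 3 + 1 / 2)), tolerance = 1e-12)
  # cross-check the whole table against TukeyHSD with unequal sizes
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(names(groups), lengths(groups))))
  ref <- TukeyHSD(aov(y ~ g, df))$g
  expect_equal(tk$p, unname(ref[, "p adj"]), tolerance = 1e-8)
})

test_that("genes lacking two surviving replicates are excluded per group", {
  cfg <- sim_config(n_genes = 30, noise_sd = 0.1, outlier_rate = 0, seed = 14)
  sim <- generate_expression(cfg)
  cl <- cleanse_dataset(sim$dataset)
  # untouched data: nothing excluded
  expect_length(filter_insufficient(cl, condition_group("dehydration"))$excluded, 0)

  # force a drop_all in R12 for one gene: excluded from rehydration only
  g <- rownames(cl$expr)[4]
  cl$mask[g, which(cl$design$condition == "R12")] <- FALSE
  deh <- filter_insufficient(cl, condition_group("dehydration"))
  reh <- filter_insufficient(cl, condition_group("rehydration"))
  expect_false(g %in% deh$excluded)
  expect_true(g %in% reh$excluded)
  # deterministic
  expect_identical(reh$excluded,
                   filter_insufficient(cl, condition_group("rehydration"))$excluded)
})

test_that("SDAT designation recovers planted effects and controls the null", {
  # complete null: no SDATs at zero noise beyond numerical ties
  cfg0 <- sim_config(n_genes = 40, noise_sd = 0,
                     archetype_weights = c(constant = 1), outlier_rate = 0,
                     seed = 19)
  cl0 <- cleanse_dataset(generate_expression(cfg0)$dataset)
  s0 <- designate_sdats(cl0)
  expect_length(s0$sdat_union, 0)

  # planted effects with noise: high sensitivity, BH keeps the FDR in check
  cfg <- sim_config(n_genes = 400, seed = 23)
  sim <- generate_expression(cfg)
  cl <- cleanse_dataset(sim$dataset)
  sd <- designate_sdats(cl)
  truth <- sim$truth
  called <- sd$sdat_union
  sens <- mean(names(truth$archetype)[truth$is_differential] %in% called)
  expect_gte(sens, 0.9)
  fdr_emp <- mean(!truth$is_differential[called])
  mc_se <- sqrt(0.05 * 0.95 / length(called))
  expect_lte(fdr_emp, 0.05 + 2 * mc_se)

  # invariants of the SDAT record
  tab <- sd$dehydration$table
  expect_true(all(tab$p_adj >= tab$p - 1e-15))
  expect_identical(tab$is_sdat, tab$p_adj < 0.05)
  expect_setequal(names(sd$dehydration$tukey), tab$gene[tab$is_sdat])
})

test_that("null ANOVA p-values are approximately uniform", {
  cfg <- sim_config(n_genes = 600, archetype_weights = c(constant = 1),
                    outlier_rate = 0, seed = 29)
  cl <- cleanse_dataset(generate_expression(cfg)$dataset)
  sd <- designate_sdats(cl)
  p <- sd$dehydration$table$p
  frac <- mean(p < 0.05)
  ci <- qbinom(c(0.005, 0.995), length(p), 0.05) / length(p)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  # BH-declared discoveries under the complete null are rare
  expect_lte(length(sd$sdat_union), 0.02 * length(p))
})
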