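test_that("the standardised-deviation bound is (n-1)/sqrt(n)", {
  expect_equal(max_abs_z_bound(3), 2 / sqrt(3))
  expect_equal(round(max_abs_z_bound(3), 2), 1.15)
  expect_equal(max_abs_z_bound(2), 1 / sqrt(2))
  expect_equal(max_abs_z_bound(4), 3 / 2)
  expect_error(max_abs_z_bound(1), ">= 2")
  # numerical maximization oracle: no random n-tuple exceeds the bound
  for (n in c(2, 4)) {
    set.seed(n)
    zmax <- max(replicate(20000, {
      x <- runif(n, -5, 5)
      max(abs(x - mean(x)) / sd(x))
    }))
    expect_lte(zmax, max_abs_z_bound(n) + 1e-9)
    expect_gt(zmax, max_abs_z_bound(n) - 0.05)  # bound is tight
  }
})

test_that("triplicate z-scores satisfy the exact identities", {
  triples <- random_triples(5000, seed = 9)
  stats <- apply(triples, 1, function(v) {
    st <- triplicate_stats(v)
    if (st$sd == 0) return(c(0, 2, 0, 0))
    c(sum(st$z), sum(st$z^2), max(abs(st$z)), sum(abs(st$z) > 1))
  })
  expect_lt(max(abs(stats[1, ])), 1e-8)          # z-scores sum to zero
  expect_lt(max(abs(stats[2, ] - 2)), 1e-8)      # sum of squares is 2
  expect_lte(max(stats[3, ]), 2 / sqrt(3) + 1e-9)  # bound never exceeded
  expect_lte(max(stats[4, ]), 1)                 # at most one outlier
})

test_that("cleanse_triplicate implements the decision rule", {
  # identical replicates: CV = 0, keep
  d <- cleanse_triplicate(c(5, 5, 5))
  expect_equal(d$action, "keep")
  expect_equal(d$trigger, "none")
  expect_equal(d$stats$cv, 0)

  # hand-computed: (10, 10, 2) has mean 7.333, sd 4.6188, cv 0.6299 > 0.5;
  # z3 = -1.1547 is the single outlier and the remaining pair (10, 10) has
  # CV 0, so the third replicate is dropped
  d2 <- cleanse_triplicate(c(10, 10, 2))
  expect_equal(d2$stats$sd, 4.6188, tolerance = 1e-4)
  expect_equal(d2$stats$cv, 0.6298, tolerance = 1e-3)
  expect_equal(d2$stats$z[3], -1.1547, tolerance = 1e-4)
  expect_equal(d2$action, "drop_one")
  expect_equal(d2$drop_index, 3L)
  expect_equal(d2$trigger, "cv_scrutiny")

  # hand-computed: (1, 6, 11) has mean 6, sd 5, cv 0.8333 > 0.75 and
  # z = (-1, 0, 1) -- no replicate exceeds |z| > 1 (strict), so the whole
  # set is excluded
  d3 <- cleanse_triplicate(c(1, 6, 11))
  expect_equal(d3$stats$cv, 5 / 6, tolerance = 1e-12)
  expect_equal(d3$stats$z, c(-1, 0, 1))
  expect_equal(d3$action, "drop_all")
  expect_equal(d3$trigger, "hard_cv")

  # scrutinised but below the hard threshold with no removable outlier:
  # kept with a flag
  v <- c(0.8, 2.0, 3.2)  # cv = 0.6, z = (-1, 0, 1)
  d4 <- cleanse_triplicate(v)
  expect_gt(d4$stats$cv, 0.5)
  expect_lt(d4$stats$cv, 0.75)
  expect_equal(d4$action, "keep")
  expect_true(d4$flagged)

  # degenerate non-positive mean: kept with a warning record
  d5 <- cleanse_triplicate(c(-2, 0, 1))
  expect_equal(d5$action, "keep")
  expect_equal(d5$trigger, "none")
  expect_true(d5$warn)
})

test_that("at most one replicate can ever be a |z| > 1 outlier", {
  triples <- random_triples(20000, seed = 13)
  m <- rowMeans(triples)
  s <- apply(triples, 1, sd)
  ok <- s > 0
  z <- (triples[ok, ] - m[ok]) / s[ok]
  expect_true(all(rowSums(abs(z) > 1) <= 1))
})

test_that("cleansing a dataset masks planted outliers and logs every triplicate", {
  cfg <- sim_config(n_genes = 200, seed = 21)
  sim <- generate_expression(cfg)
  cl <- cleanse_dataset(sim$dataset)
  expect_equal(nrow(cl$decisions), 200 * 8)

  ol <- sim$truth$outliers
  key <- paste(cl$decisions$gene, cl$decisions$condition)
  hit <- cl$decisions[match(paste(ol$gene, ol$condition), key), ]
  flag_rate <- mean(hit$action == "drop_one" & hit$drop_index == ol$replicate)
  expect_gte(flag_rate, 0.95)

  # masked values are exactly the dropped replicates
  expect_equal(sum(!cl$mask), cl$summary$n_values_excluded)
  expect_equal(cl$summary$n_single_outliers +
                 3 * cl$summary$n_complete_exclusions, sum(!cl$mask))
})

test_that("zero-noise data produces no exclusions", {
  cfg <- sim_config(n_genes = 50, noise_sd = 0, outlier_rate = 0, seed = 3)
  cl <- cleanse_dataset(generate_expression(cfg)$dataset)
  expect_equal(sum(!cl$mask), 0)
  expect_true(all(cl$decisions$action == "keep"))
})

test_that("removing the flagged outlier usually lowers the CV (reported, not asserted)", {
  # empirical analogue of the claim that removal of the flagged replicate
  # moderates the CV with very high probability; the fraction is reported
  # via the decision rule itself: every drop_one had post-removal CV <= 0.5
  triples <- abs(random_triples(20000, seed = 17)) + 0.1  # positive means
  res <- apply(triples, 1, function(v) {
    m <- mean(v); s <- sd(v)
    if (s == 0 || s / m <= 0.5) return(c(0, 0))
    z <- (v - m) / s
    out <- which(abs(z) > 1)
    if (length(out) != 1) return(c(0, 0))
    pair <- v[-out]
    c(1, sd(pair) / mean(pair) < s / m)
  })
  eligible <- sum(res[1, ])
  improved <- sum(res[2, ])
  expect_gt(eligible, 100)
  expect_gt(improved / eligible, 0.5)  # weak sanity floor only
})
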