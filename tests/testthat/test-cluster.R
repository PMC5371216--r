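test_that("pearson correlation matches hand computation and its contracts", {
  x <- c(1, 2, 3)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 0.9820, tolerance = 1e-4)
  expect_error(pearson(1:2, 1:2), "length")
  expect_error(pearson(c(1, 1, 1), 1:3), "constant")
})

test_that("threshold clustering groups identical profiles and splits opposites", {
  p <- rbind(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5))  # r = 1
  cl <- threshold_cluster(p)
  expect_length(cl$members, 1)
  expect_equal(cl$avg_r[1], 1)

  p2 <- rbind(a = c(1, 2, 3, 4), b = -c(1, 2, 3, 4))
  cl2 <- threshold_cluster(p2)
  expect_length(cl2$members, 2)

  # degenerate constant profile becomes a singleton
  p3 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 5, 5))
  cl3 <- threshold_cluster(p3)
  expect_equal(sort(lengths(cl3$members), decreasing = TRUE), c(2, 1))
  expect_true("c" %in% unlist(cl3$members[lengths(cl3$members) == 1]))
})

test_that("planted two-archetype profiles are recovered exactly", {
  base1 <- c(0, 1, 2, 2, 2, 1.5)
  base2 <- c(0, 0, 0.2, 0.5, 2, 0.1)
  set.seed(41)
  p <- rbind(
    g1 = base1 + rnorm(6, sd = 0.05), g2 = base1 + rnorm(6, sd = 0.05),
    g3 = base1 + rnorm(6, sd = 0.05),
    g4 = base2 + rnorm(6, sd = 0.05), g5 = base2 + rnorm(6, sd = 0.05),
    g6 = base2 + rnorm(6, sd = 0.05)
  )
  cl <- threshold_cluster(p, r_min = 0.85)
  expect_length(cl$members, 2)
  expect_setequal(cl$members[[which(vapply(cl$members, function(m)
    "g1" %in% m, TRUE))]], c("g1", "g2", "g3"))

  # exhaustive-partition oracle: the output is one of the partitions in
  # which every multi-member block satisfies the criterion, and the planted
  # partition is itself valid
  parts <- all_partitions(6L)
  ids <- rownames(p)
  valid <- Filter(function(pt) {
    all(vapply(pt, function(blk) {
      r <- avg_pairwise_r(p, ids[blk])
      is.na(r) || r >= 0.85
    }, TRUE))
  }, parts)
  canon <- function(blocks) {
    blocks <- lapply(blocks, sort)
    paste(sort(vapply(blocks, paste, "", collapse = ",")), collapse = "|")
  }
  got <- canon(cl$members)
  expect_true(got %in% vapply(valid, function(pt)
    canon(lapply(pt, function(b) ids[b])), ""))
  expect_true(canon(list(c("g1", "g2", "g3"), c("g4", "g5", "g6"))) %in%
                vapply(valid, function(pt)
                  canon(lapply(pt, function(b) ids[b])), ""))
})

test_that("every emitted multi-profile cluster satisfies the validity criterion", {
  set.seed(47)
  for (rep in 1:5) {
    p <- matrix(rnorm(40 * 6), 40, 6,
                dimnames = list(sprintf("g%02d", 1:40), NULL))
    # add some shared structure so merges happen
    p[1:15, ] <- p[1:15, ] * 0.2 + rep(c(0, 1, 2, 3, 3, 2), each = 15)
    cl <- threshold_cluster(p, r_min = 0.85)
    for (m in cl$members) {
      if (length(m) < 2) next
      expect_gte(avg_pairwise_r(p, m), 0.85 - 1e-10)
    }
    # partition covers every profile exactly once
    expect_setequal(unlist(cl$members), rownames(p))
    expect_equal(sum(lengths(cl$members)), nrow(p))
  }
})

test_that("clustering is deterministic and affine-invariant", {
  set.seed(53)
  p <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  p[1:8, ] <- p[1:8, ] * 0.1 + rep(c(0, 1, 2, 2, 1, 0.5), each = 8)
  cl1 <- threshold_cluster(p)
  cl2 <- threshold_cluster(p)
  expect_identical(cl1$members, cl2$members)
  # uniform affine rescaling of single profiles leaves Pearson unchanged
  p3 <- p
  p3[3, ] <- 2.5 * p3[3, ] + 7
  p3[11, ] <- 0.1 * p3[11, ] - 4
  cl3 <- threshold_cluster(p3)
  expect_identical(cl1$members, cl3$members)
})

test_that("cluster summaries count sizes and large-cluster coverage", {
  p <- rbind(a = 1:4, b = 1:4 + 0.01, c = c(4, 1, 3, 2))
  cl <- threshold_cluster(p)
  cs <- cluster_summary(cl, k = 2)
  expect_equal(cs$n_clusters, 2)
  expect_equal(cs$n_clusters_ge_k, 1)
  expect_equal(cs$frac_in_large, 2 / 3)

  singles <- threshold_cluster(rbind(a = c(1, 2, 3), b = -c(1, 2, 3)))
  cs2 <- cluster_summary(singles, k = 2)
  expect_equal(max(lengths(singles$members)), 1)
  expect_equal(cs2$frac_in_large, 0)

  one <- threshold_cluster(rbind(a = 1:4, b = 1:4))
  expect_equal(cluster_summary(one, k = 2)$frac_in_large, 1)
})

test_that("zero-noise synthetic data recovers the planted archetype clusters exactly", {
  cfg <- sim_config(n_genes = 120, noise_sd = 0, outlier_rate = 0, seed = 31)
  sim <- generate_expression(cfg)
  cl <- cleanse_dataset(sim$dataset)
  diff_genes <- names(sim$truth$archetype)[sim$truth$is_differential]
  prof <- condition_profiles(cl, condition_group("dehydration"),
                             genes = diff_genes)
  out <- threshold_cluster(prof)
  planted <- split(diff_genes, sim$truth$archetype[diff_genes])
  expect_length(out$members, length(planted))
  for (m in out$members) {
    expect_true(any(vapply(planted, function(pl) setequal(pl, m), TRUE)))
  }
})
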