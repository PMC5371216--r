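#' Pearson correlation between two profiles
#'
#' Sample Pearson correlation; errors on constant input (the caller treats a
#' degenerate profile as a singleton).
#'
#' @param x,y equal-length numeric vectors of length >= 3.
#' @return correlation in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("profiles must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant profile")
  stats::cor(x, y)
}

#' Per-condition mean profiles of the cleansed data
#'
#' @param cleansed a `cleansed_dataset`.
#' @param group a [condition_group()].
#' @param genes genes to include (default all retained by
#'   [filter_insufficient()]).
#' @return numeric matrix, genes x conditions, of means of the surviving
#'   log2 replicate values.
#' @export
condition_profiles <- function(cleansed, group, genes = NULL) {
  stopifnot(inherits(cleansed, "cleansed_dataset"))
  if (is.null(genes)) genes <- filter_insufficient(cleansed, group)$retained
  prof <- sapply(group$conditions, function(cn) {
    cols <- which(cleansed$design$condition == cn)
    vals <- cleansed$expr[genes, cols, drop = FALSE]
    msk <- cleansed$mask[genes, cols, drop = FALSE]
    rowSums(vals * msk) / rowSums(msk)
  })
  rownames(prof) <- genes
  prof
}

#' Threshold-validity correlation clustering
#'
#' Greedy agglomeration of expression profiles under an explicit validity
#' criterion: at every step the merge that would yield the highest average
#' pairwise Pearson correlation in the merged set is performed, but only if
#' that average is at least `r_min`; the procedure stops when no acceptable
#' merge remains. Every emitted multi-profile cluster is therefore guaranteed
#' to satisfy the average-pairwise criterion, which is asserted before
#' returning. Ties are broken towards the candidate containing the
#' lexicographically smallest profile id, so the output is deterministic.
#' Degenerate (constant) profiles become singletons.
#'
#' @param profiles numeric matrix of profiles (rows, with rownames as ids) x
#'   condition means; at least 3 columns for a meaningful correlation.
#' @param r_min minimum average pairwise Pearson correlation of a cluster
#'   (default 0.85).
#' @return list of class `cluster_assignment`: `cluster` (named integer
#'   vector, one id per profile), `members` (list of id vectors, ordered by
#'   decreasing size then first member), `avg_r` (per-cluster average
#'   pairwise correlation; NA for singletons), `r_min`.
#' @export
threshold_cluster <- function(profiles, r_min = 0.85) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 1) stop("need at least one profile")
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- sprintf("p%04d", seq_len(nrow(profiles)))
  rownames(profiles) <- ids

  sds <- apply(profiles, 1, stats::sd)
  degenerate <- !is.finite(sds) | sds == 0
  active_ids <- ids[!degenerate]

  clusters <- as.list(active_ids)  # each element: member id vector
  if (length(active_ids) > 1) {
    R <- stats::cor(t(profiles[active_ids, , drop = FALSE]))
    # cross[i, j]: sum of pairwise correlations between clusters i and j;
    # diag holds the within-cluster sum of pairwise correlations.
    cross <- R
    diag(cross) <- 0
    sizes <- rep(1L, length(clusters))
    within <- rep(0, length(clusters))
    first <- active_ids  # lexicographically smallest member per cluster

    repeat {
      nc <- length(clusters)
      if (nc < 2) break
      # candidate merged average pairwise r for every cluster pair
      np <- outer(sizes, sizes, function(a, b) choose(a + b, 2))
      tot <- outer(within, within, "+") + cross
      cand <- tot / np
      diag(cand) <- -Inf
      best <- max(cand)
      if (best < r_min) break
      hits <- which(cand == best, arr.ind = TRUE)
      hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
      key1 <- pmin(first[hits[, 1]], first[hits[, 2]])
      key2 <- pmax(first[hits[, 1]], first[hits[, 2]])
      pick <- order(key1, key2)[1]
      i <- hits[pick, 1]; j <- hits[pick, 2]

      clusters[[i]] <- c(clusters[[i]], clusters[[j]])
      within[i] <- within[i] + within[j] + cross[i, j]
      sizes[i] <- sizes[i] + sizes[j]
      first[i] <- min(first[i], first[j])
      cross[i, ] <- cross[i, ] + cross[j, ]
      cross[, i] <- cross[, i] + cross[, j]
      cross[i, i] <- 0
      clusters <- clusters[-j]
      within <- within[-j]; sizes <- sizes[-j]; first <- first[-j]
      cross <- cross[-j, -j, drop = FALSE]
    }
  }
  clusters <- c(clusters, as.list(ids[degenerate]))

  # order clusters by decreasing size, then first member id
  ord <- order(-lengths(clusters),
               vapply(clusters, function(m) sort(m)[1], ""))
  clusters <- lapply(clusters[ord], sort)

  avg_r <- vapply(clusters, function(m) {
    if (length(m) < 2) return(NA_real_)
    Rm <- stats::cor(t(profiles[m, , drop = FALSE]))
    mean(Rm[upper.tri(Rm)])
  }, 0)
  # validity: every multi-profile cluster satisfies the criterion
  stopifnot(all(avg_r[!is.na(avg_r)] >= r_min - 1e-12))

  assign <- integer(nrow(profiles))
  names(assign) <- ids
  for (ci in seq_along(clusters)) assign[clusters[[ci]]] <- ci
  structure(list(cluster = assign, members = clusters, avg_r = avg_r,
                 r_min = r_min),
            class = "cluster_assignment")
}

#' Summarise a cluster assignment
#'
#' @param assignment a `cluster_assignment`.
#' @param k size threshold for "large" clusters (default 10).
#' @return list with `n_clusters`, `size_table` (histogram of cluster
#'   sizes), `n_clusters_ge_k`, `frac_in_large` (fraction of profiles that
#'   sit in clusters of size >= k), and `k`.
#' @export
cluster_summary <- function(assignment, k = 10L) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  sizes <- lengths(assignment$members)
  list(n_clusters = length(sizes),
       size_table = table(sizes),
       n_clusters_ge_k = sum(sizes >= k),
       frac_in_large = sum(sizes[sizes >= k]) / sum(sizes),
       k = k)
}
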