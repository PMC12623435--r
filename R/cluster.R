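#' Cluster-permutation test configuration
#'
#' @param n_permutations number of random permutations (1024 by default).
#' @param cluster_alpha alpha of the parametric cluster-forming threshold.
#' @param seed optional seed for the permutation RNG.
#' @return an object of class `cluster_config`.
#' @export
cluster_config <- function(n_permutations = 1024, cluster_alpha = 0.05,
                           seed = NULL) {
  stopifnot(n_permutations >= 1, cluster_alpha > 0, cluster_alpha < 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 cluster_alpha = cluster_alpha, seed = seed),
            class = "cluster_config")
}

#' Per-cell paired t map and auto threshold
#'
#' One-sample t statistics on within-subject difference maps (subjects x
#' channels x time), with the cluster-forming threshold set parametrically:
#' the two-sided t quantile at `cluster_alpha` with `n - 1` degrees of
#' freedom. Zero-variance cells yield t = 0 (they cannot carry evidence).
#'
#' @param diffs array `n_subjects x channels x time` of condition
#'   differences.
#' @param cluster_alpha threshold-forming alpha.
#' @return list with `stat` (channels x time), `threshold`, `df`.
#' @export
stat_map_paired_t <- function(diffs, cluster_alpha = 0.05) {
  stopifnot(length(dim(diffs)) == 3, dim(diffs)[1] >= 2)
  n <- dim(diffs)[1]
  m <- apply(diffs, c(2, 3), mean)
  s <- apply(diffs, c(2, 3), stats::sd)
  tmap <- ifelse(s > 0, m / (s / sqrt(n)), 0)
  if (any(s == 0)) warning("zero-variance cells set to t = 0")
  list(stat = tmap, threshold = stats::qt(1 - cluster_alpha / 2, n - 1),
       df = n - 1)
}

#' Per-cell one-way repeated-measures F map and auto threshold
#'
#' For each (channel, time) cell, `F = MS_condition / MS_(condition x
#' subject)` over the three within-subject conditions, thresholded at the
#' `1 - cluster_alpha` F quantile with `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom.
#'
#' @param cond_list list of `k >= 2` arrays `n x channels x time` (the
#'   study design uses k = 3).
#' @param cluster_alpha threshold-forming alpha.
#' @return list with `stat`, `threshold`, `df` (length-2).
#' @export
stat_map_rm_F <- function(cond_list, cluster_alpha = 0.05) {
  k <- length(cond_list)
  stopifnot(k >= 2)
  dm <- dim(cond_list[[1]])
  n <- dm[1]
  p <- dm[2] * dm[3]
  X <- lapply(cond_list, function(a) matrix(a, n, p))
  tot <- Reduce(`+`, X)
  grand <- colSums(tot) / (n * k)
  ss_cond <- matrix(0, 1, p)
  for (c in seq_len(k)) {
    ss_cond <- ss_cond + n * (colMeans(X[[c]]) - grand)^2
  }
  subj_mean <- tot / k
  ss_subj <- k * colSums(sweep(subj_mean, 2, grand)^2)
  ss_tot <- Reduce(`+`, lapply(X, function(m) colSums(sweep(m, 2, grand)^2)))
  ss_err <- pmax(ss_tot - as.vector(ss_cond) - ss_subj, 0)
  df <- c(k - 1, (k - 1) * (n - 1))
  mse <- ss_err / df[2]
  # cells with (numerically) zero within-subject variance carry no evidence
  tol <- ss_tot * 1e-12 / df[2]
  fmap <- ifelse(mse > tol & mse > 0, (as.vector(ss_cond) / df[1]) / mse, 0)
  list(stat = matrix(fmap, dm[2], dm[3]),
       threshold = stats::qf(1 - cluster_alpha, df[1], df[2]),
       df = df)
}

#' Form spatio-temporal clusters from a statistic map
#'
#' Groups supra-threshold cells into connected components where two cells
#' connect if they share a channel and are temporally adjacent, or share a
#' time point on adjacent channels. For two-sided maps, positive and
#' negative exceedances form separate clusters.
#'
#' @param stat channels x time statistic matrix.
#' @param threshold cluster-forming threshold (`> 0`).
#' @param adjacency a [channel_adjacency()] graph.
#' @param tail `"two.sided"` (t maps) or `"positive"` (F maps).
#' @return list with `labels` (integer channels x time matrix, 0 =
#'   sub-threshold) and `clusters` data.frame (`id`, `sign`, `mass`,
#'   `n_cells`, `n_sensors`, `t_start`, `t_end` in column indices).
#' @export
form_clusters <- function(stat, threshold, adjacency,
                          tail = c("two.sided", "positive")) {
  tail <- match.arg(tail)
  stopifnot(is.matrix(stat), nrow(stat) == length(adjacency$names))
  res <- form_clusters_cpp(stat, threshold, adjacency$neighbors,
                           if (tail == "two.sided") 0L else 1L)
  lab <- res$labels
  n_cl <- length(res$mass)
  if (n_cl == 0) {
    cl <- data.frame(id = integer(0), sign = integer(0), mass = numeric(0),
                     n_cells = integer(0), n_sensors = integer(0),
                     t_start = integer(0), t_end = integer(0))
  } else {
    cl <- do.call(rbind, lapply(seq_len(n_cl), function(i) {
      cells <- which(lab == i, arr.ind = TRUE)
      data.frame(id = i, sign = res$sign[i], mass = res$mass[i],
                 n_cells = nrow(cells),
                 n_sensors = length(unique(cells[, 1])),
                 t_start = min(cells[, 2]), t_end = max(cells[, 2]))
    }))
  }
  list(labels = lab, clusters = cl)
}

#' Spatio-temporal cluster-based permutation test
#'
#' Mass-univariate test of paired differences (`test = "paired_t"`, null
#' built from random per-subject sign flips) or of a three-condition
#' within-subject effect (`test = "rm_F"`, null from random within-subject
#' condition-label permutations). The cluster statistic is the mass (sum of
#' cell statistics); the null distribution is the per-permutation maximum
#' absolute cluster mass across the map (both tails for t), and cluster
#' p-values are `(1 + #(null >= observed)) / (1 + n_permutations)`.
#'
#' @param data for `"paired_t"`: an array `n x channels x time` of
#'   within-subject differences; for `"rm_F"`: a list of three such arrays
#'   (one per condition).
#' @param adjacency a [channel_adjacency()] graph.
#' @param cfg a [cluster_config()].
#' @param test test family.
#' @param times optional time axis (ms) used to report cluster extents.
#' @return an object of class `cluster_test_result`: list with `clusters`
#'   (data.frame incl. `p`), `stat_map`, `threshold`, `df`,
#'   `null_max_mass`, `labels`.
#' @export
permutation_test <- function(data, adjacency, cfg = cluster_config(),
                             test = c("paired_t", "rm_F"), times = NULL) {
  test <- match.arg(test)
  if (test == "paired_t") {
    stopifnot(length(dim(data)) == 3)
    dm <- dim(data)
    n <- dm[1]
    if (n < 2) stop("need at least 2 subjects")
    if (2^n < cfg$n_permutations) {
      warning("fewer distinct sign flips (2^", n, ") than requested ",
              "permutations; running anyway")
    }
    thr <- stats::qt(1 - cfg$cluster_alpha / 2, n - 1)
    res <- with_seed(cfg$seed, {
      perm_cluster_t_cpp(matrix(data, n, dm[2] * dm[3]), dm[2], dm[3],
                         thr, adjacency$neighbors, cfg$n_permutations)
    })
    df <- n - 1
    tail <- "two.sided"
  } else {
    stopifnot(is.list(data), length(data) == 3)
    dm <- dim(data[[1]])
    n <- dm[1]
    thr <- stats::qf(1 - cfg$cluster_alpha, 2, 2 * (n - 1))
    X <- lapply(data, function(a) matrix(a, n, dm[2] * dm[3]))
    res <- with_seed(cfg$seed, {
      perm_cluster_f_cpp(X[[1]], X[[2]], X[[3]], dm[2], dm[3],
                         thr, adjacency$neighbors, cfg$n_permutations)
    })
    df <- c(2, 2 * (n - 1))
    tail <- "positive"
  }
  lab <- res$clusters$labels
  masses <- res$clusters$mass
  signs <- res$clusters$sign
  nullmax <- res$null_max_mass
  n_cl <- length(masses)
  clusters <- if (n_cl == 0) {
    data.frame(id = integer(0), sign = integer(0), mass = numeric(0),
               n_cells = integer(0), n_sensors = integer(0),
               t_start = integer(0), t_end = integer(0), p = numeric(0))
  } else {
    do.call(rbind, lapply(seq_len(n_cl), function(i) {
      cells <- which(lab == i, arr.ind = TRUE)
      data.frame(id = i, sign = signs[i], mass = masses[i],
                 n_cells = nrow(cells),
                 n_sensors = length(unique(cells[, 1])),
                 t_start = min(cells[, 2]), t_end = max(cells[, 2]),
                 p = (1 + sum(nullmax >= abs(masses[i]))) /
                   (1 + cfg$n_permutations))
    }))
  }
  if (!is.null(times) && nrow(clusters) > 0) {
    clusters$t_start_ms <- times[clusters$t_start]
    clusters$t_end_ms <- times[clusters$t_end]
  }
  structure(
    list(clusters = clusters, stat_map = res$stat_map, threshold = thr,
         df = df, null_max_mass = nullmax, labels = lab, tail = tail,
         n_permutations = cfg$n_permutations),
    class = "cluster_test_result"
  )
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat("<cluster_test_result> threshold", round(x$threshold, 3),
      "|", x$n_permutations, "permutations\n")
  cl <- x$clusters
  if (nrow(cl) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    cl <- cl[order(cl$p, -abs(cl$mass)), ]
    for (i in seq_len(min(nrow(cl), 10))) {
      r <- cl[i, ]
      ext <- if (!is.null(r$t_start_ms)) {
        sprintf("%g-%g ms", r$t_start_ms, r$t_end_ms)
      } else {
        sprintf("cols %d-%d", r$t_start, r$t_end)
      }
      cat(sprintf("  %s cluster, %s, %d sensors, mass %.1f, p = %.4g\n",
                  if (r$sign > 0) "positive" else "negative",
                  ext, r$n_sensors, r$mass, r$p))
    }
  }
  invisible(x)
}

#' Serialize a cluster test result to JSON
#'
#' @param x a `cluster_test_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_result <- function(x, path) {
  jsonlite::write_json(
    list(threshold = x$threshold, df = x$df,
         n_permutations = x$n_permutations, clusters = x$clusters),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
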