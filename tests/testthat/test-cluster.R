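mont6 <- mini_montage()
adj6 <- channel_adjacency(mont6)

test_that("adjacency graph is symmetric, irreflexive, and connected by default", {
  m30 <- default_montage()
  adj <- channel_adjacency(m30)
  expect_true(isSymmetric(adj$matrix))
  expect_true(all(!diag(adj$matrix)))
  deg <- rowSums(adj$matrix)
  expect_gte(stats::median(deg), 4)
  expect_lte(stats::median(deg), 6)
  expect_true(rovingmmn:::adjacency_connected(adj))
  # radius limits
  expect_equal(sum(channel_adjacency(m30, radius = 1e-6)$matrix), 0)
  full <- channel_adjacency(m30, radius = 100)
  expect_true(all(full$matrix[upper.tri(full$matrix)]))
  expect_error(channel_adjacency(m30, radius = 0), "positive")
})

test_that("paired t map matches hand arithmetic on a 3-subject toy", {
  # 3 subjects, 2 channels, 2 time points
  d <- array(0, c(3, 2, 2))
  d[, 1, 1] <- c(1, 2, 3)
  d[, 1, 2] <- c(0, 0, 3)
  d[, 2, 1] <- c(-1, -2, -3)
  d[, 2, 2] <- c(5, 5, 5)
  res <- suppressWarnings(stat_map_paired_t(d))
  hand_t <- function(x) mean(x) / (stats::sd(x) / sqrt(length(x)))
  expect_equal(res$stat[1, 1], hand_t(c(1, 2, 3)), tolerance = 1e-12)
  expect_equal(res$stat[1, 2], hand_t(c(0, 0, 3)), tolerance = 1e-12)
  expect_equal(res$stat[2, 1], hand_t(c(-1, -2, -3)), tolerance = 1e-12)
  # zero-variance cell maps to t = 0 with a warning
  expect_warning(res2 <- stat_map_paired_t(d), "zero-variance")
  expect_equal(res2$stat[2, 2], 0)
  expect_equal(res$df, 2)
})

test_that("auto thresholds are the parametric quantiles", {
  d <- array(stats::rnorm(35 * 2 * 3), c(35, 2, 3))
  expect_equal(stat_map_paired_t(d)$threshold, stats::qt(0.975, 34))
  expect_equal(round(stat_map_paired_t(d)$threshold, 3), 2.032)
  l3 <- lapply(1:3, function(i) array(stats::rnorm(35 * 2 * 3), c(35, 2, 3)))
  expect_equal(stat_map_rm_F(l3)$threshold, stats::qf(0.95, 2, 68))
})

test_that("identical conditions give null stat maps", {
  a <- array(stats::rnorm(6 * 6 * 10), c(6, 6, 10))
  expect_warning(tmap <- stat_map_paired_t(a - a)$stat, "zero-variance")
  expect_true(all(tmap == 0))
  f <- stat_map_rm_F(list(a, a, a))$stat
  expect_true(all(f == 0))
})

test_that("2-condition F map is the squared paired-t map", {
  set.seed(4)
  a <- array(stats::rnorm(8 * 6 * 12), c(8, 6, 12))
  b <- array(stats::rnorm(8 * 6 * 12), c(8, 6, 12))
  f2 <- stat_map_rm_F(list(a, b))
  t2 <- stat_map_paired_t(a - b)
  expect_equal(f2$stat, t2$stat^2, tolerance = 1e-8)
  expect_equal(f2$df, c(1, 7))
})

test_that("F maps from the permutation engine match the R decomposition", {
  set.seed(5)
  l3 <- lapply(1:3, function(i) array(stats::rnorm(7 * 6 * 9), c(7, 6, 9)))
  engine <- permutation_test(l3, adj6, cluster_config(n_permutations = 4, seed = 1),
                             test = "rm_F")
  expect_equal(engine$stat_map, stat_map_rm_F(l3)$stat, tolerance = 1e-10)
})

test_that("cluster formation matches the brute-force flood-fill oracle", {
  set.seed(1234)
  adj_small <- channel_adjacency(mont6, radius = 0.4)
  for (rep in 1:300) {
    stat <- matrix(stats::rnorm(6 * 40, sd = 1.4), 6, 40)
    cl <- form_clusters(stat, 2, adj_small, tail = "two.sided")
    oracle <- cluster_oracle(stat, 2, adj_small$matrix, "two.sided")
    expect_equal(sort(cl$clusters$mass), oracle, tolerance = 1e-12)
  }
  # positive-tail maps
  for (rep in 1:100) {
    stat <- matrix(stats::rexp(6 * 30), 6, 30)
    cl <- form_clusters(stat, 2.2, adj_small, tail = "positive")
    oracle <- cluster_oracle(stat, 2.2, adj_small$matrix, "positive")
    expect_equal(sort(cl$clusters$mass), oracle, tolerance = 1e-12)
  }
})

test_that("simple cluster topologies come out right", {
  adj_none <- channel_adjacency(
    structure(list(names = c("a", "b"), pos = rbind(c(-1, 0), c(1, 0)),
                   roi = "a"), class = "montage"), radius = 0.5)
  stat <- matrix(0, 2, 5)
  stat[1, 2] <- 3
  one <- form_clusters(stat, 2, adj_none)
  expect_equal(nrow(one$clusters), 1)
  expect_equal(one$clusters$mass, 3)
  expect_equal(one$clusters$n_cells, 1)
  # disjoint channels and disjoint times -> two clusters
  stat[2, 5] <- 4
  two <- form_clusters(stat, 2, adj_none)
  expect_equal(nrow(two$clusters), 2)
  # temporal contiguity merges on the same channel
  stat2 <- matrix(0, 2, 5)
  stat2[1, 2:4] <- c(3, 2.5, 3)
  expect_equal(nrow(form_clusters(stat2, 2, adj_none)$clusters), 1)
  # opposite signs never merge
  stat3 <- matrix(0, 2, 5)
  stat3[1, 2] <- 3
  stat3[1, 3] <- -3
  expect_equal(nrow(form_clusters(stat3, 2, adj_none)$clusters), 2)
})

test_that("permutation p-values are floored at 1/(n_perm + 1) and reproducible", {
  set.seed(10)
  d <- array(stats::rnorm(12 * 6 * 30), c(12, 6, 30)) + 2  # huge global effect
  res <- permutation_test(d, adj6, cluster_config(n_permutations = 200, seed = 3))
  expect_gte(nrow(res$clusters), 1)
  expect_equal(min(res$clusters$p), 1 / 201, tolerance = 1e-12)
  res2 <- permutation_test(d, adj6, cluster_config(n_permutations = 200, seed = 3))
  expect_identical(res$clusters, res2$clusters)
  expect_true(all(res$clusters$p >= 1 / 201 & res$clusters$p <= 1))
})

test_that("negating the data mirrors the t map and cluster signs", {
  set.seed(11)
  d <- array(stats::rnorm(10 * 6 * 25), c(10, 6, 25))
  d[, 2, 10:15] <- d[, 2, 10:15] + 1.5
  a <- permutation_test(d, adj6, cluster_config(n_permutations = 50, seed = 2))
  b <- permutation_test(-d, adj6, cluster_config(n_permutations = 50, seed = 2))
  expect_equal(a$stat_map, -b$stat_map, tolerance = 1e-12)
  expect_equal(sort(a$clusters$mass), sort(-b$clusters$mass), tolerance = 1e-12)
  expect_equal(sum(a$clusters$sign > 0), sum(b$clusters$sign < 0))
})

test_that("scaling an injected effect up never shrinks the max cluster mass", {
  set.seed(21)
  noise <- array(stats::rnorm(10 * 6 * 40), c(10, 6, 40))
  bump <- array(0, c(10, 6, 40))
  bump[, 1:3, 15:25] <- 1
  masses <- vapply(c(0, 0.5, 1, 2), function(a) {
    m <- stat_map_paired_t(noise + a * bump)
    cl <- form_clusters(m$stat, m$threshold, adj6)
    if (nrow(cl$clusters)) max(abs(cl$clusters$mass)) else 0
  }, numeric(1))
  expect_true(all(diff(masses) >= 0))
})

test_that("too few subjects for the requested permutations warns but runs", {
  d <- array(stats::rnorm(4 * 6 * 10), c(4, 6, 10))
  expect_warning(
    res <- permutation_test(d, adj6, cluster_config(n_permutations = 100, seed = 1)),
    "fewer distinct"
  )
  expect_s3_class(res, "cluster_test_result")
})

test_that("cluster results serialize to JSON", {
  set.seed(10)
  d <- array(stats::rnorm(12 * 6 * 30), c(12, 6, 30)) + 2
  res <- permutation_test(d, adj6, cluster_config(n_permutations = 50, seed = 3),
                          times = seq(-100, 190, by = 10))
  f <- tempfile(fileext = ".json")
  write_cluster_result(res, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$n_permutations, 50)
  expect_equal(nrow(back$clusters), nrow(res$clusters))
  unlink(f)
})
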