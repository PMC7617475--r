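# Normalization, differential calling, kinetic clustering and half-time
# estimation.

test_that("size factors match the median-of-ratios definition", {
  tp <- c(0, 2)
  # identical samples -> all size factors 1
  mu <- matrix(rep(c(100, 40, 10, 500, 80), 2), ncol = 2)
  tc <- make_tc(mu, tp, n_reps = 1)
  norm <- normalize_counts(tc)
  expect_equal(unique(norm$size_factor), 1)
  # doubled sample -> factors proportional 1:2
  set.seed(1)
  counts_a <- rpois(100, 60) + 1
  tc2 <- tibble::tibble(
    gene = rep(sprintf("g%03d", 1:100), each = 2),
    timepoint = rep(c(0, 2), 100),
    replicate = 1,
    count = as.vector(rbind(counts_a, 2 * counts_a))
  )
  norm2 <- normalize_counts(tc2)
  sf <- tapply(norm2$size_factor, norm2$timepoint, unique)
  expect_equal(unname(sf[["2"]] / sf[["0"]]), 2)
  # random matrix against the direct re-computation
  set.seed(2)
  m <- matrix(rnbinom(50 * 4, mu = 80, size = 10), 50, 4)
  tc3 <- make_tc(matrix(m, 50, 4), c(0, 1, 2, 6), n_reps = 1)
  norm3 <- normalize_counts(tc3)
  got <- tapply(norm3$size_factor,
                paste(norm3$timepoint, norm3$replicate), unique)
  want <- size_factors_direct(m)
  expect_equal(as.vector(got[c("0 1", "1 1", "2 1", "6 1")]),
               unname(want), tolerance = 1e-12)
  expect_error(normalize_counts(make_tc(matrix(0, 5, 2), c(0, 2))),
               "zero")
})

test_that("identical counts at both timepoints flag no genes", {
  mu <- matrix(rep(c(100, 250, 30, 900), 2), ncol = 2)
  tc <- make_tc(mu, c(0, 2), n_reps = 2)
  de <- call_differential_genes(tc, 0, 2)
  expect_true(all(de$direction == "ns"))
  expect_true(all(de$p_value == 1))
})

test_that("a strong repression is detected in nearly all repeats", {
  hits <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    counts <- c(rnbinom(2, mu = 1000, size = 20),
                rnbinom(2, mu = 125, size = 20))
    tc <- tibble::tibble(
      gene = "g1",
      timepoint = rep(c(0, 2), each = 2),
      replicate = rep(1:2, 2),
      count = counts,
      size_factor = 1,
      norm_count = counts
    )
    de <- call_differential_genes(tc, 0, 2)
    de$direction == "down" && de$p_adjusted < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("direction respects the printed thresholds exactly", {
  sim <- simulate_timecourse(sim_config(seed = 3, n_genes = 400))
  de <- call_differential_genes(normalize_counts(sim$counts), 0, 24,
                                alpha = 0.01, min_abs_log2fc = 1)
  down <- de$direction == "down"
  up <- de$direction == "up"
  expect_true(all(de$p_adjusted[down] < 0.01 &
                    de$log2_fold_change[down] < -1))
  expect_true(all(de$p_adjusted[up] < 0.01 & de$log2_fold_change[up] > 1))
  ns <- de$direction == "ns"
  expect_true(all(de$p_adjusted[ns] >= 0.01 |
                    abs(de$log2_fold_change[ns]) <= 1))
  expect_true(all(de$p_adjusted >= de$p_value))
})

test_that("BH adjustment matches a direct step-up implementation", {
  for (i in 1:5) {
    set.seed(i)
    p <- runif(200)^2
    expect_equal(p.adjust(p, "BH"), bh_direct(p), tolerance = 1e-12)
  }
})

test_that("clustering recovers planted kinetic families", {
  cfg <- sim_config(
    seed = 5, n_genes = 1000,
    timepoints = c(0, 0.5, 0.75, 1, 2, 4, 8, 12, 24, 48, 72)
  )
  sim <- simulate_timecourse(cfg)
  tc <- normalize_counts(sim$counts)
  de <- call_differential_genes(tc, 0, 72)
  cl <- cluster_kinetics(tc, de, k = 4, seed = 5)
  merged <- dplyr::left_join(cl$members, sim$truth, by = "gene")
  expect_gte(mclust::adjustedRandIndex(merged$cluster, merged$class), 0.9)
  labels <- cl$clusters$label[cl$clusters$retained]
  expect_setequal(labels, c("fast_repressed", "slow_repressed",
                            "activated", "slow_activated"))
  expect_true(all(cl$trajectories$mean_scaled >= 0 &
                    cl$trajectories$mean_scaled <= 1))
})

test_that("a rise-and-fall cluster is removed as non-monotonic", {
  tp <- c(0, 1, 2, 4, 8, 24)
  shapes <- list(
    down = c(400, 320, 220, 120, 60, 50),
    up = c(50, 70, 120, 220, 320, 400),
    bump = c(100, 260, 400, 400, 260, 100)
  )
  mu <- do.call(rbind, lapply(shapes, function(s) {
    matrix(rep(s, each = 60), nrow = 60, byrow = FALSE)
  }))
  tc <- make_tc(mu, tp, n_reps = 2, dispersion = 0.02, seed = 8)
  cl <- suppressWarnings(
    cluster_kinetics(normalize_counts(tc),
                     unique(tc$gene), k = 3, seed = 2)
  )
  expect_true(any(cl$clusters$label == "removed_non_monotonic"))
  removed <- cl$clusters[cl$clusters$label == "removed_non_monotonic", ]
  expect_true(all(abs(removed$rho) < 0.8))
  expect_true(all(cl$clusters$retained[cl$clusters$direction == "down" &
                                         cl$clusters$cluster !=
                                           removed$cluster]))
})

test_that("shared trajectories give near-identical cluster means", {
  tp <- c(0, 1, 2, 6)
  s <- c(300, 200, 120, 60)
  mu <- matrix(rep(s, each = 40), nrow = 40)
  tc <- make_tc(mu, tp, n_reps = 2, dispersion = 0.005, seed = 3)
  # unit size factors: when every gene shares the trajectory,
  # median-of-ratios would (correctly) absorb it as a depth artefact
  tc$size_factor <- 1
  tc$norm_count <- tc$count
  cl <- cluster_kinetics(tc, unique(tc$gene), k = 2, seed = 1)
  tr <- tidyr::pivot_wider(cl$trajectories[, c("cluster", "timepoint",
                                               "mean_scaled")],
                           names_from = "cluster",
                           values_from = "mean_scaled")
  # k-means splits pure noise, and selecting on noise separates the two
  # cluster means slightly; they must agree far more closely than truly
  # distinct kinetic families do (>= 0.5 apart on the scaled axis)
  expect_lt(max(abs(tr[[2]] - tr[[3]])), 0.2)
})

test_that("cluster assignment ignores row and replicate order", {
  sim <- simulate_timecourse(sim_config(seed = 9, n_genes = 300))
  tc <- normalize_counts(sim$counts)
  de <- call_differential_genes(tc, 0, 24)
  cl1 <- cluster_kinetics(tc, de, k = 4, seed = 4)
  set.seed(1)
  shuffled <- tc[sample(nrow(tc)), ]
  shuffled$replicate <- ifelse(shuffled$replicate == 1, 2, 1)
  cl2 <- cluster_kinetics(shuffled, de, k = 4, seed = 4)
  m <- dplyr::left_join(cl1$members, cl2$members, by = "gene")
  expect_equal(mclust::adjustedRandIndex(m$cluster.x, m$cluster.y), 1)
})

test_that("half-time estimation interpolates the first half crossing", {
  expect_equal(estimate_t_half(c(1, 0.9, 0.5, 0.1, 0), c(0, 0.5, 1, 2, 6)),
               1)
  expect_equal(estimate_t_half(seq(1, 0, length.out = 5),
                               seq(0, 2, length.out = 5)), 1)
  # rising trajectory
  expect_equal(estimate_t_half(c(0, 0.25, 0.5, 0.75, 1), 0:4), 2)
  # the half level lies between the observed extremes, so a monotone
  # trajectory always attains it: a shallow decay crosses at its midpoint
  expect_equal(estimate_t_half(c(1, 0.95, 0.9), c(0, 1, 2)), 1)
  # affine time equivariance on random monotone trajectories
  for (i in 1:20) {
    set.seed(i)
    v <- sort(runif(8), decreasing = TRUE)
    tp <- sort(runif(8, 0, 24))
    expect_equal(estimate_t_half(v, 2 * tp), 2 * estimate_t_half(v, tp),
                 tolerance = 1e-12)
  }
})

test_that("min-max scaling is idempotent and flags constants", {
  x <- c(0, 0.3, 0.7, 1)
  expect_equal(tfresponse:::minmax_scale(x), x)
  expect_null(tfresponse:::minmax_scale(rep(2, 5)))
})
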