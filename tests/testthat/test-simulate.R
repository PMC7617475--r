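# Synthetic-data generators: determinism, ground-truth conservation,
# noise model moments, kinetic trajectory shape, and telegraph sampling.

small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 120, n_reg_genes = 50,
             genome_length = 5e6, n_peaks = 300, n_cells = 200, ...)
}

test_that("identical configurations give byte-identical outputs", {
  cfg <- small_cfg(seed = 7)
  expect_identical(simulate_timecourse(cfg), simulate_timecourse(cfg))
  expect_identical(simulate_peaks(cfg), simulate_peaks(cfg))
  p <- telegraph_params(1, 4)
  expect_identical(simulate_fish(p, p, 50, seed = 3),
                   simulate_fish(p, p, 50, seed = 3))
  # and a different seed changes them
  expect_false(identical(simulate_timecourse(cfg),
                         simulate_timecourse(small_cfg(seed = 8))))
})

test_that("truth labels match the configured class proportions", {
  cfg <- sim_config(seed = 2, n_genes = 997)
  sim <- simulate_timecourse(cfg)
  counts <- table(sim$truth$class)
  expected <- cfg$class_proportions * cfg$n_genes
  expect_equal(sum(counts), cfg$n_genes)
  for (cl in names(expected)) {
    expect_lte(abs(counts[[cl]] - expected[[cl]]), 1)
  }
})

test_that("count noise follows the negative-binomial variance function", {
  set.seed(11)
  m <- 50
  alpha <- 0.1
  draws <- tfresponse:::rnbinom_disp(10000, rep(m, 10000), alpha)
  expect_lt(abs(var(draws) - (m + alpha * m^2)) / (m + alpha * m^2), 0.05)
  expect_lt(abs(mean(draws) - m) / m, 0.05)
})

test_that("zero dispersion reproduces rounded model means exactly", {
  cfg <- small_cfg(seed = 4, nb_dispersion = 0)
  sim <- simulate_timecourse(cfg)
  joined <- dplyr::left_join(sim$counts, sim$truth, by = "gene")
  mu <- purrr::pmap_dbl(
    list(joined$base_mean, joined$class, joined$t_half, joined$timepoint),
    function(b, cl, th, tp) {
      mean_trajectory(b, cl, ifelse(is.na(th), 1, th), tp,
                      cfg$response_floor)
    }
  )
  expect_identical(joined$count, round(mu))
})

test_that("scaled noiseless trajectories cross 0.5 exactly at t-half", {
  # the grid must carry the trajectory essentially to its plateau for
  # min-max scaling to reproduce the asymptotic extremes
  dense <- c(seq(0, 30, by = 0.002), seq(31, 600, by = 1))
  cases <- list(c("fast_repressed", 0.75), c("slow_repressed", 12),
                c("activated", 3), c("slow_activated", 14.5))
  for (cs in cases) {
    th <- as.numeric(cs[2])
    mu <- mean_trajectory(100, cs[1], th, dense)
    scaled <- (mu - min(mu)) / (max(mu) - min(mu))
    expect_equal(estimate_t_half(scaled, dense), th, tolerance = 1e-3)
  }
  expect_error(mean_trajectory(-5, "fast_repressed", 1, 0:2), "positive")
  expect_error(mean_trajectory(10, "oscillating", 1, 0:2), "unknown")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(class_proportions = c(fast_repressed = 0.7,
                                                activated = 0.2)),
               "sum to 1")
  expect_error(sim_config(class_proportions = c(mystery = 1)), "unknown")
  expect_error(sim_config(timepoints = c(1, 2, 3)), "start at 0")
  expect_error(sim_config(timepoints = c(0, 2, 2)), "increasing")
  expect_error(telegraph_params(-1, 2), "non-negative")
})

test_that("zero motif coupling equalises expected motif density", {
  cfg <- sim_config(seed = 5, n_reg_genes = 80, genome_length = 1e7,
                    n_peaks = 1500, motif_density_effect = 0,
                    baseline_logodds = qlogis(0.3),
                    motif_rate = c(near_fast = 0.8, background = 0.8))
  pk <- simulate_peaks(cfg)
  d <- pk$peaks$motif_density[pk$peaks$class_true == "decreased"]
  u <- pk$peaks$motif_density[pk$peaks$class_true == "unchanged"]
  expect_gt(length(d), 100)
  expect_lt(abs(mean(d) - mean(u)) / mean(u), 0.1)
})

test_that("unit enhancer speedup equalises enhancer and promoter decay", {
  cfg <- sim_config(seed = 6, n_reg_genes = 150, genome_length = 1.2e7,
                    n_peaks = 1200, enhancer_speedup = 1,
                    baseline_logodds = qlogis(0.5))
  pk <- simulate_peaks(cfg)
  dec <- pk$peaks[pk$peaks$class_true == "decreased" &
                    pk$peaks$element %in% c("promoter", "enhancer"), ]
  atac <- pk$counts[pk$counts$assay == "atac" &
                      pk$counts$peak_id %in% dec$peak_id, ]
  late <- tapply(atac$count[atac$timepoint == 2],
                 atac$peak_id[atac$timepoint == 2], mean)
  base <- tapply(atac$count[atac$timepoint == 0],
                 atac$peak_id[atac$timepoint == 0], mean)
  rel <- dec
  rel$frac <- late[rel$peak_id] / pmax(base[rel$peak_id], 1)
  mean_frac <- tapply(rel$frac, rel$element, mean)
  expect_lt(abs(mean_frac[["enhancer"]] - mean_frac[["promoter"]]), 0.05)
})

test_that("simulated peaks never overlap and motifs are non-negative", {
  pk <- simulate_peaks(small_cfg(seed = 9))
  expect_true(all(pk$peaks$start < pk$peaks$end))
  expect_true(all(diff(pk$peaks$start) >= 0))
  expect_true(all(pk$peaks$start[-1] >= pk$peaks$end[-nrow(pk$peaks)]))
  expect_true(all(pk$peaks$motif_count >= 0))
})

test_that("burst states follow the telegraph stationary probability", {
  # absorbing OFF state
  fs0 <- simulate_fish(telegraph_params(0, 3), telegraph_params(0, 1),
                       n_cells = 200, seed = 1)
  expect_identical(sum(fs0$condition0$burst), 0L)
  expect_identical(sum(fs0$condition1$burst), 0L)
  # symmetric rates: fraction near 0.5 within the binomial 99% CI at n=700
  fs <- simulate_fish(telegraph_params(2, 2), telegraph_params(2, 2),
                      n_cells = 700, seed = 2)
  ci_half_width <- qnorm(0.995) * sqrt(0.25 / 1400)
  expect_lt(abs(mean(fs$condition0$burst) - 0.5), ci_half_width)
  # halving k_on: closed-form stationary fractions, both within 3 SE
  p0 <- telegraph_stationary_fraction(1, 4)
  p1 <- telegraph_stationary_fraction(0.5, 4)
  fs2 <- simulate_fish(telegraph_params(1, 4), telegraph_params(0.5, 4),
                       n_cells = 5000, seed = 3)
  expect_lt(abs(mean(fs2$condition0$burst) - p0),
            3 * sqrt(p0 * (1 - p0) / 10000))
  expect_lt(abs(mean(fs2$condition1$burst) - p1),
            3 * sqrt(p1 * (1 - p1) / 10000))
  # features present iff bursting
  expect_true(all(is.na(
    fs$condition0$Intensity_MaxIntensity[!fs$condition0$burst]
  )))
  expect_true(all(
    fs$condition0$Intensity_MaxIntensity[fs$condition0$burst] > 0
  ))
})

test_that("empirical on-fraction converges to the stationary closed form", {
  pk <- telegraph_params(1.2, 2.8)
  p <- telegraph_stationary_fraction(pk)
  occ <- telegraph_trajectory(pk, n_switches = 10000, seed = 5)
  expect_lt(abs(occ - p), 0.02)
})
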