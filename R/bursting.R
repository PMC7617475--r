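# Single-molecule burst statistics: burst fraction and size from
# allele-level spot-feature tables, the exact 2x2 test, and the
# frequency-vs-size modulation report.

validate_fish_table <- function(tbl) {
  need <- c("cell_id", "allele", "burst",
            "Intensity_MaxIntensity", "AreaShape_MeanRadius")
  stopifnot(all(need %in% names(tbl)))
  if (nrow(tbl) == 0) {
    abort("FISH table is empty")
  }
  per_cell <- table(tbl$cell_id)
  if (any(per_cell != 2)) {
    abort("every cell must contribute exactly 2 allele rows")
  }
  invisible(tbl)
}

#' Burst fraction and sizes from an allele-level FISH table
#'
#' Burst fraction is the number of bursting alleles divided by the number of
#' alleles (2 x total cells). Burst sizes are collected for the bursting
#' alleles via [burst_size()].
#'
#' @param tbl Tibble `(cell_id, allele, burst, Intensity_MaxIntensity,
#'   AreaShape_MeanRadius)` with exactly two allele rows per cell.
#' @return One-row tibble of class `burst_stats`: `n_cells`, `n_alleles`,
#'   `n_bursts`, `burst_fraction`, and `sizes` (list column).
#' @export
#' @examples
#' fs <- simulate_fish(telegraph_params(1, 4), telegraph_params(0.5, 4),
#'                     n_cells = 50, seed = 1)
#' burst_fraction(fs$condition0)
burst_fraction <- function(tbl) {
  validate_fish_table(tbl)
  n_cells <- length(unique(tbl$cell_id))
  n_alleles <- 2L * n_cells
  bursts <- tbl[tbl$burst, , drop = FALSE]
  out <- tibble(
    n_cells = n_cells,
    n_alleles = n_alleles,
    n_bursts = nrow(bursts),
    burst_fraction = nrow(bursts) / n_alleles,
    sizes = list(burst_size(bursts))
  )
  class(out) <- c("burst_stats", class(out))
  out
}

#' Burst size of bursting alleles
#'
#' Defined as the sum of the spot's maximum intensity and mean radius
#' (heterogeneous units, reported as-is).
#'
#' @param tbl FISH-table rows, all of which must be bursting.
#' @return Numeric vector of burst sizes.
#' @export
#' @examples
#' burst_size(tibble::tibble(
#'   cell_id = 1, allele = 1, burst = TRUE,
#'   Intensity_MaxIntensity = 10, AreaShape_MeanRadius = 2
#' ))
burst_size <- function(tbl) {
  stopifnot(all(c("burst", "Intensity_MaxIntensity",
                  "AreaShape_MeanRadius") %in% names(tbl)))
  if (nrow(tbl) == 0) {
    return(numeric(0))
  }
  if (!all(tbl$burst)) {
    abort("burst_size() is defined only for bursting alleles")
  }
  tbl$Intensity_MaxIntensity + tbl$AreaShape_MeanRadius
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the fixed-margins hypergeometric model,
#' using the probability-ordering convention: the sum of probabilities of
#' all tables with the same margins whose probability does not exceed the
#' observed table's. Computed with log-space factorials, stable for totals
#' up to at least 10,000.
#'
#' @param table2x2 A 2x2 matrix of non-negative integer counts (or a
#'   length-4 vector, filled column-wise).
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact(matrix(c(10, 10, 90, 90), 2))  # identical proportions -> 1
fisher_exact <- function(table2x2) {
  m <- matrix(as.numeric(table2x2), 2, 2)
  if (any(m < 0) || any(m != round(m)) || any(!is.finite(m))) {
    abort("counts must be non-negative integers")
  }
  r1 <- sum(m[1, ])
  r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  n <- r1 + r2
  if (n == 0) {
    return(1)
  }
  k_min <- max(0, c1 - r2)
  k_max <- min(r1, c1)
  ks <- k_min:k_max
  logp <- lgamma(r1 + 1) - lgamma(ks + 1) - lgamma(r1 - ks + 1) +
    lgamma(r2 + 1) - lgamma(c1 - ks + 1) - lgamma(r2 - c1 + ks + 1) -
    (lgamma(n + 1) - lgamma(c1 + 1) - lgamma(n - c1 + 1))
  obs <- logp[ks == m[1, 1]]
  min(sum(exp(logp[logp <= obs + 1e-7])), 1)
}

#' Compare burst statistics between two conditions
#'
#' Tests the burst fraction with Fisher's exact test on the 2x2 table of
#' bursting vs non-bursting alleles by condition, and the burst sizes with
#' an unpaired two-sided t-test (pooled variance by default; Welch by
#' flag). The modulation verdict is `frequency` when only the fraction
#' differs at level `alpha`, `size` when only the sizes differ, `both`, or
#' `none`. When either condition has no bursts the size test is undefined
#' and reported as `NA`.
#'
#' @param table0,table1 FISH tables for the two conditions.
#' @param alpha Significance level for the verdict (default 0.01).
#' @param size_test `"student"` (pooled variance, default) or `"welch"`.
#' @return One-row tibble of class `burst_comparison`: per-condition cell
#'   counts, fractions and mean sizes, `fisher_p`, `size_t_p`, `modulation`.
#' @export
#' @examples
#' fs <- simulate_fish(telegraph_params(1, 4), telegraph_params(0.5, 4),
#'                     n_cells = 700, seed = 1)
#' compare_conditions(fs$condition0, fs$condition1)
compare_conditions <- function(table0, table1, alpha = 0.01,
                               size_test = c("student", "welch")) {
  size_test <- match.arg(size_test)
  s0 <- burst_fraction(table0)
  s1 <- burst_fraction(table1)
  tab <- matrix(c(
    s0$n_bursts, s1$n_bursts,
    s0$n_alleles - s0$n_bursts, s1$n_alleles - s1$n_bursts
  ), 2, 2)
  fp <- fisher_exact(tab)
  sizes0 <- s0$sizes[[1]]
  sizes1 <- s1$sizes[[1]]
  sp <- if (length(sizes0) >= 2 && length(sizes1) >= 2) {
    t.test(sizes0, sizes1, var.equal = (size_test == "student"))$p.value
  } else {
    NA_real_
  }
  modulation <- if (is.na(sp)) {
    if (fp < alpha) "frequency" else "none"
  } else if (fp < alpha && sp < alpha) {
    "both"
  } else if (fp < alpha) {
    "frequency"
  } else if (sp < alpha) {
    "size"
  } else {
    "none"
  }
  out <- tibble(
    n_cells0 = s0$n_cells, n_cells1 = s1$n_cells,
    fraction0 = s0$burst_fraction, fraction1 = s1$burst_fraction,
    size_mean0 = if (length(sizes0)) mean(sizes0) else NA_real_,
    size_mean1 = if (length(sizes1)) mean(sizes1) else NA_real_,
    fisher_p = fp, size_t_p = sp, modulation = modulation
  )
  class(out) <- c("burst_comparison", class(out))
  out
}

#' Stationary ON probability of the telegraph model
#'
#' Closed form `k_on / (k_on + k_off)`: the long-run probability that a
#' two-state promoter switching ON at rate `k_on` and OFF at rate `k_off`
#' is observed in the active state.
#'
#' @param k_on,k_off Non-negative switching rates, not both zero. A
#'   [telegraph_params()] object may be passed as `k_on`.
#' @return The stationary ON probability.
#' @export
#' @examples
#' telegraph_stationary_fraction(1, 4)
telegraph_stationary_fraction <- function(k_on, k_off = NULL) {
  if (inherits(k_on, "telegraph_params")) {
    k_off <- k_on$k_off
    k_on <- k_on$k_on
  }
  check_non_negative(c(k_on, k_off), "k_on/k_off")
  if (k_on + k_off == 0) {
    abort("k_on and k_off cannot both be zero")
  }
  k_on / (k_on + k_off)
}
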