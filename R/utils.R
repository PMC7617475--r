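# Internal helpers shared across modules: seeded substreams, interval
# arithmetic on 0-based half-open coordinates, and the negative-binomial
# Wald test used by both the expression and the accessibility stages.

#' Derive a reproducible substream seed from a master seed and a stage name
#'
#' All randomness in the package flows from a single master seed; each
#' stochastic stage draws from its own named substream so that disabling or
#' reordering stages does not perturb the others.
#'
#' @param seed Master integer seed.
#' @param name Character substream name (e.g. `"timecourse"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1000003
  as.integer((abs(seed) %% 1000000 * 2017 + h * 7919 + 13) %% 2147483647)
}

# Evaluate `expr` under `seed` without touching the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# ---- interval helpers (0-based half-open, single toy chromosome) ----------

# Merge possibly-overlapping sorted-or-not intervals into a disjoint set.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0) {
    return(list(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  s <- start[o]
  e <- end[o]
  ms <- s[1]
  me <- e[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- s[i]
      me <- e[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

# Does each query interval [qs, qe) overlap ANY target interval? Targets are
# merged first, so arbitrary target sets are handled.
overlaps_any <- function(q_start, q_end, t_start, t_end) {
  m <- merge_intervals(t_start, t_end)
  if (length(m$start) == 0) {
    return(rep(FALSE, length(q_start)))
  }
  idx <- findInterval(q_start, m$start)
  hit_left <- idx >= 1 & q_start < m$end[pmax(idx, 1)]
  nxt <- pmin(idx + 1, length(m$start))
  hit_right <- idx < length(m$start) & m$start[nxt] < q_end
  hit_left | hit_right
}

# Index of the disjoint sorted target interval containing position `pos`,
# NA when none. Used for summit-in-peak lookups.
interval_index_of <- function(pos, t_start, t_end) {
  idx <- findInterval(pos, t_start)
  ok <- idx >= 1 & pos < t_end[pmax(idx, 1)]
  ifelse(ok, idx, NA_integer_)
}

# Midpoint of a 0-based half-open interval, per the BED convention used
# throughout: floor((start + end) / 2).
interval_midpoint <- function(start, end) {
  floor((start + end) / 2)
}

# ---- negative-binomial Wald test ------------------------------------------

# Per-feature two-group NB Wald test on normalized counts with
# method-of-moments dispersion (floored), used for both differential
# expression and differential accessibility/acetylation.
#
# Dispersion: per-feature MoM estimates at 2 replicates have a single
# degree of freedom and are useless individually, so by default the median
# of the per-feature estimates is shared across features ("common"); the
# raw per-feature estimator remains available.
#
# `df` is a long tibble with columns <id_col>, timepoint, replicate,
# norm_count. Returns one row per feature with log2 fold change (t vs
# t_ref), Wald p-value and BH-adjusted p-value.
nb_wald_test <- function(df, id_col, t_ref, t,
                         dispersion = c("common", "per_feature")) {
  dispersion <- match.arg(dispersion)
  stopifnot(id_col %in% names(df), "norm_count" %in% names(df))
  tps <- unique(df$timepoint)
  if (!(t_ref %in% tps) || !(t %in% tps)) {
    abort("both `t_ref` and `t` must be present in the data")
  }
  sub <- df[df$timepoint %in% c(t_ref, t), , drop = FALSE]
  grp <- ifelse(sub$timepoint == t_ref, "ref", "alt")
  nrep <- table(grp, sub[[id_col]])
  if (any(nrep < 2)) {
    abort("at least 2 replicates per timepoint are required")
  }

  agg <- sub %>%
    mutate(.grp = grp) %>%
    group_by(.data[[id_col]], .data$.grp) %>%
    summarise(
      m = mean(.data$norm_count), v = var(.data$norm_count), n = n(),
      .groups = "drop"
    ) %>%
    # method-of-moments dispersion pooled over both groups, floored
    mutate(d = ifelse(.data$m > 0, (.data$v - .data$m) / .data$m^2,
                      NA_real_)) %>%
    tidyr::pivot_wider(
      id_cols = dplyr::all_of(id_col), names_from = ".grp",
      values_from = c("m", "n", "d")
    )
  per_feature_disp <- rowMeans(cbind(agg$d_ref, agg$d_alt), na.rm = TRUE)
  per_feature_disp[!is.finite(per_feature_disp)] <- 0
  disp <- if (dispersion == "common") {
    rep(max(median(per_feature_disp), 1e-8), nrow(agg))
  } else {
    pmax(per_feature_disp, 1e-8)
  }
  # Wald statistic on log mean difference; +0.5 pseudocount guards zeros.
  a0 <- agg$m_ref + 0.5
  a1 <- agg$m_alt + 0.5
  se2 <- (1 / a0 + disp) / agg$n_ref + (1 / a1 + disp) / agg$n_alt
  z <- (log(a1) - log(a0)) / sqrt(se2)
  res <- tibble(
    id = agg[[id_col]],
    base_mean = (agg$m_ref * agg$n_ref + agg$m_alt * agg$n_alt) /
      (agg$n_ref + agg$n_alt),
    log2_fold_change = log2(a1 / a0),
    dispersion = disp,
    stat = z,
    p_value = 2 * pnorm(-abs(z))
  )
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  names(res)[names(res) == "id"] <- id_col
  res
}

# Uniform tie-safe checks used by constructors.
check_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("`", what, "` must be positive and finite"))
  }
  invisible(x)
}

check_non_negative <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(paste0("`", what, "` must be non-negative and finite"))
  }
  invisible(x)
}
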