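# Kinetic analysis of count time courses: normalization, differential
# calling, K-means clustering of scaled trajectories, monotonicity
# filtering, and half-maximal response times.

#' Median-of-ratios normalization of a count time course
#'
#' Computes one size factor per sample (timepoint x replicate) as the median
#' across features of the ratio of the count to the feature's geometric mean
#' over all samples; all-zero features are excluded from the reference.
#' Adds `size_factor` and `norm_count` (= count / size_factor) columns.
#'
#' @param tc Long tibble with columns `timepoint`, `replicate`, `count` and
#'   an identifier column (default `gene`).
#' @param id_col Name of the identifier column.
#' @return `tc` with `size_factor` and `norm_count` columns added.
#' @export
#' @examples
#' tc <- simulate_timecourse(sim_config(seed = 1, n_genes = 30))$counts
#' head(normalize_counts(tc))
normalize_counts <- function(tc, id_col = "gene") {
  stopifnot(all(c(id_col, "timepoint", "replicate", "count") %in% names(tc)))
  wide <- tc %>%
    mutate(sample = paste(.data$timepoint, .data$replicate, sep = "_")) %>%
    tidyr::pivot_wider(
      id_cols = dplyr::all_of(id_col), names_from = "sample",
      values_from = "count"
    )
  m <- as.matrix(wide[, -1])
  if (all(m == 0)) {
    abort("all counts are zero; size factors are undefined")
  }
  keep <- rowSums(m > 0) == ncol(m)  # geometric mean defined only here
  if (!any(keep)) {
    abort("no feature has nonzero counts in every sample")
  }
  loggeo <- rowMeans(log(m[keep, , drop = FALSE]))
  sf <- apply(m[keep, , drop = FALSE], 2, function(col) {
    median(exp(log(col) - loggeo))
  })
  sf_tbl <- tibble(sample = colnames(m), size_factor = unname(sf))
  tc %>%
    mutate(sample = paste(.data$timepoint, .data$replicate, sep = "_")) %>%
    left_join(sf_tbl, by = "sample") %>%
    mutate(norm_count = .data$count / .data$size_factor) %>%
    select(-"sample")
}

#' Call differentially expressed genes between two timepoints
#'
#' Per-gene negative-binomial Wald test on normalized counts (method-of-
#' moments dispersion, floored at 1e-8) comparing `t` against `t_ref`, with
#' Benjamini-Hochberg adjustment across genes. A gene is called `down` when
#' `p_adjusted < alpha` and `log2_fold_change < -min_abs_log2fc`, `up` for
#' the mirrored rule, and `ns` otherwise.
#'
#' @param tc Count time course (normalized with [normalize_counts()];
#'   normalization is applied if the `norm_count` column is absent).
#' @param t_ref,t Reference and test timepoints (hours), both present with
#'   at least two replicates.
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param min_abs_log2fc Minimum |log2 fold change| (default 1).
#' @param id_col Identifier column name.
#' @return Tibble of class `tf_de` with columns `gene`, `base_mean`,
#'   `log2_fold_change`, `p_value`, `p_adjusted`, `direction`.
#' @export
#' @examples
#' tc <- simulate_timecourse(sim_config(seed = 1, n_genes = 100))$counts
#' de <- call_differential_genes(tc, t_ref = 0, t = 24)
#' table(de$direction)
call_differential_genes <- function(tc, t_ref, t, alpha = 0.01,
                                    min_abs_log2fc = 1, id_col = "gene") {
  if (!"norm_count" %in% names(tc)) {
    tc <- normalize_counts(tc, id_col = id_col)
  }
  res <- nb_wald_test(tc, id_col, t_ref, t)
  res <- res %>%
    mutate(direction = case_when(
      .data$p_adjusted < alpha & .data$log2_fold_change < -min_abs_log2fc ~
        "down",
      .data$p_adjusted < alpha & .data$log2_fold_change > min_abs_log2fc ~
        "up",
      TRUE ~ "ns"
    )) %>%
    select(-"dispersion", -"stat")
  class(res) <- c("tf_de", class(res))
  res
}

# Min-max scale a vector to [0, 1]; NULL signals a constant trajectory.
minmax_scale <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) {
    return(NULL)
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Cluster differential genes by kinetic behaviour
#'
#' Replicate-averages normalized counts per gene and timepoint, scales each
#' gene's trajectory to \[0, 1\] by min-max, and partitions genes with
#' seeded K-means (25 restarts). Scaling is applied to the linear normalized
#' counts by default: for trajectories that approach a floor or ceiling
#' exponentially, the min-max scaled linear trajectory crosses 0.5 at the
#' underlying half-time, whereas a log transform shifts the crossing (by a
#' factor close to 2 for strong repression), so half-times estimated from
#' log-scaled trajectories would not be comparable across response depths.
#' `transform = "log2"` reproduces the log2(x + 1) convention for display
#' purposes.
#'
#' Each cluster's summary trajectory is computed from baseline-relative
#' ratios rather than by averaging the per-gene scaled trajectories: the
#' member genes' `(value + 0.5) / (value at t0 + 0.5)` trajectories are
#' averaged and the cluster mean is then min-max scaled to \[0, 1\].
#' Per-gene min-max scaling uses observed extremes, which noise inflates,
#' and averaging those scaled trajectories biases the half-crossing early;
#' scaling the averaged ratio trajectory lets the noise cancel across
#' genes first. Clusters are relabelled by behaviour: the
#' sign of the net change splits repressed from activated, and the rank of
#' the cluster-mean half-time splits fast from slow. Clusters whose mean
#' trajectory is not monotone in time (|Spearman rho| < `rho_min`) are
#' labelled `removed_non_monotonic` and flagged for exclusion downstream,
#' mirroring the removal of treatment-artefact clusters.
#'
#' @param tc Normalized count time course.
#' @param de_genes Character vector of differential gene identifiers (or a
#'   `tf_de` table, from which non-`ns` genes are taken).
#' @param k Number of clusters (default 5).
#' @param seed Integer seed for K-means.
#' @param rho_min Monotonicity threshold on |Spearman rho| of the cluster
#'   mean trajectory against time (default 0.8).
#' @param transform `"linear"` (default) or `"log2"` (log2(x + 1))
#'   transformation of normalized counts before scaling.
#' @param id_col Identifier column name.
#' @return A list of class `kinetic_clusters`:
#'   * `clusters` — per-cluster label, size, net direction, Spearman rho,
#'     `t_half` (hours, `NA` when the half level is never crossed) and
#'     `retained`;
#'   * `trajectories` — per-cluster mean scaled trajectory with 95% CI;
#'   * `members` — gene-to-cluster assignment.
#' @export
#' @examples
#' sim <- simulate_timecourse(sim_config(seed = 1, n_genes = 200))
#' tc <- normalize_counts(sim$counts)
#' de <- call_differential_genes(tc, 0, 24)
#' cl <- cluster_kinetics(tc, de, k = 5, seed = 1)
#' cl$clusters
cluster_kinetics <- function(tc, de_genes, k = 5, seed = 1, rho_min = 0.8,
                             transform = c("linear", "log2"),
                             id_col = "gene") {
  transform <- match.arg(transform)
  if (inherits(de_genes, "tf_de")) {
    de_genes <- de_genes[[id_col]][de_genes$direction != "ns"]
  }
  if (k < 2) {
    abort("`k` must be at least 2")
  }
  if (length(de_genes) < k) {
    abort("need at least `k` differential genes to cluster")
  }
  if (!"norm_count" %in% names(tc)) {
    tc <- normalize_counts(tc, id_col = id_col)
  }
  tp <- sort(unique(tc$timepoint))
  traj <- tc %>%
    filter(.data[[id_col]] %in% de_genes) %>%
    group_by(.data[[id_col]], .data$timepoint) %>%
    summarise(value = if (transform == "log2") {
      mean(log2(.data$norm_count + 1))
    } else {
      mean(.data$norm_count)
    }, .groups = "drop") %>%
    arrange(.data[[id_col]], .data$timepoint)
  mat <- matrix(traj$value, ncol = length(tp), byrow = TRUE,
                dimnames = list(unique(traj[[id_col]]), tp))
  scaled <- t(apply(mat, 1, function(x) {
    s <- minmax_scale(x)
    if (is.null(s)) rep(NA_real_, length(x)) else s
  }))
  flat <- rowSums(is.na(scaled)) > 0
  if (any(flat)) {
    warn(paste(sum(flat), "gene(s) with constant trajectories dropped"))
    scaled <- scaled[!flat, , drop = FALSE]
  }
  if (nrow(scaled) < k) {
    abort("fewer than `k` non-constant trajectories remain")
  }

  km <- with_seed(seed, kmeans(scaled, centers = k, nstart = 25,
                               iter.max = 50))
  members <- tibble(
    gene = rownames(scaled),
    cluster = as.integer(km$cluster)
  )
  names(members)[1] <- id_col

  # baseline-relative ratio trajectories for the cluster summaries
  ratios <- (mat[rownames(scaled), , drop = FALSE] + 0.5) /
    (mat[rownames(scaled), 1] + 0.5)

  per_cluster <- map(seq_len(k), function(cl) {
    sub <- ratios[km$cluster == cl, , drop = FALSE]
    mu_r <- colMeans(sub)
    se_r <- apply(sub, 2, sd) / sqrt(nrow(sub))
    rng <- range(mu_r)
    if (rng[2] - rng[1] <= 0) {       # flat cluster mean: undefined scaling
      mu <- rep(0.5, length(mu_r))
      se <- rep(0, length(mu_r))
    } else {
      mu <- (mu_r - rng[1]) / (rng[2] - rng[1])
      se <- se_r / (rng[2] - rng[1])
    }
    rho <- suppressWarnings(cor(mu_r, tp, method = "spearman"))
    list(
      cluster = cl, n_genes = nrow(sub), mean = mu, se = se,
      rho = rho,
      direction = if (mu[length(mu)] >= mu[1]) "up" else "down",
      t_half = estimate_t_half(mu, tp)
    )
  })

  info <- map(per_cluster, function(p) {
    tibble(
      cluster = p$cluster, n_genes = p$n_genes, direction = p$direction,
      rho = p$rho, t_half = p$t_half,
      retained = is.finite(p$rho) && abs(p$rho) >= rho_min
    )
  }) %>% list_rbind()

  # behaviour labels: fast/slow by t_half rank within each retained direction
  info$label <- NA_character_
  for (dir in c("down", "up")) {
    idx <- which(info$retained & info$direction == dir)
    if (length(idx) == 0) next
    ord <- idx[order(info$t_half[idx])]
    lab <- if (dir == "down") {
      c("fast_repressed", rep("slow_repressed", length(ord) - 1))
    } else {
      c("activated", rep("slow_activated", length(ord) - 1))
    }
    info$label[ord] <- lab
  }
  info$label[!info$retained] <- "removed_non_monotonic"
  info$label <- make.unique(info$label, sep = "_")

  trajectories <- map(per_cluster, function(p) {
    tibble(
      cluster = p$cluster,
      label = info$label[info$cluster == p$cluster],
      timepoint = tp,
      mean_scaled = unname(p$mean),
      ci_low = pmax(unname(p$mean - 1.96 * p$se), 0),
      ci_high = pmin(unname(p$mean + 1.96 * p$se), 1)
    )
  }) %>% list_rbind()

  members <- members %>% left_join(select(info, "cluster", "label"),
                                   by = "cluster")
  structure(
    list(clusters = info, trajectories = trajectories, members = members),
    class = "kinetic_clusters"
  )
}

#' Half-maximal response time of a trajectory
#'
#' The half level is the midpoint of the trajectory's extremes,
#' `(max + min) / 2`; the returned time is the first crossing of that level,
#' linearly interpolated between the flanking timepoints. Works for
#' decreasing and increasing trajectories alike.
#'
#' @param values Per-timepoint trajectory values.
#' @param timepoints Matching timepoints (hours), strictly increasing.
#' @return First crossing time in hours, or `NA` when the half level is
#'   never crossed (reported, not raised).
#' @export
#' @examples
#' estimate_t_half(c(1, 0.9, 0.5, 0.1, 0), c(0, 0.5, 1, 2, 6))
estimate_t_half <- function(values, timepoints) {
  stopifnot(length(values) == length(timepoints), length(values) >= 2,
            all(diff(timepoints) > 0))
  half <- (max(values) + min(values)) / 2
  d <- values - half
  for (i in seq_len(length(values) - 1)) {
    if (d[i] == 0) {
      return(timepoints[i])
    }
    if (d[i] * d[i + 1] <= 0) {
      frac <- d[i] / (d[i] - d[i + 1])
      return(timepoints[i] + frac * (timepoints[i + 1] - timepoints[i]))
    }
  }
  if (d[length(d)] == 0) {
    return(timepoints[length(d)])
  }
  NA_real_
}
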