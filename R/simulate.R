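# Synthetic-data generators. These emulate the statistical structure of a
# TF-induction study — clustered repression/activation kinetics in nascent
# transcription, motif-coupled loss of chromatin accessibility, faster
# acetylation loss at enhancers than promoters, and two-state telegraph
# bursting — with known ground truth, so that every analysis stage can be
# validated by parameter recovery.

#' Telegraph-model parameters
#'
#' Two-state promoter model: the promoter switches ON at rate `k_on` and OFF
#' at rate `k_off` (per hour); snapshots of an allele are bursting with
#' stationary probability `k_on / (k_on + k_off)`. Bursting alleles carry
#' spot features (maximum intensity and mean radius) drawn around the
#' configured means.
#'
#' @param k_on,k_off Switching rates (per hour), non-negative.
#' @param burst_intensity_mean Mean maximum spot intensity (a.u.).
#' @param burst_radius_mean Mean spot radius (pixels).
#' @param noise_sd Standard deviation of the feature noise.
#' @return A `telegraph_params` object (named list).
#' @export
#' @examples
#' telegraph_params(k_on = 1, k_off = 4)
telegraph_params <- function(k_on, k_off, burst_intensity_mean = 10,
                             burst_radius_mean = 2, noise_sd = 1) {
  check_non_negative(c(k_on, k_off, noise_sd), "rates/noise_sd")
  check_positive(c(burst_intensity_mean, burst_radius_mean), "feature means")
  structure(
    list(
      k_on = k_on, k_off = k_off,
      burst_intensity_mean = burst_intensity_mean,
      burst_radius_mean = burst_radius_mean,
      noise_sd = noise_sd
    ),
    class = "telegraph_params"
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators with validated
#' defaults. The defaults encode the study conditions the package is built
#' around: four kinetic gene classes with half-maximal response times of
#' 0.75 h (fast-repressed), 12 h (slow-repressed), 3 h (activated) and
#' 14.5 h (slow-activated), embedded in a majority of non-responding genes
#' (as in any transcriptome, and required for median-of-ratios size factors
#' to be anchored); duplicate libraries over a 24 h time course;
#' accessibility loss whose probability increases with embedded binding-motif
#' density; enhancers losing signal twice as fast as promoters; and an
#' induction that halves the telegraph ON-rate without changing burst size.
#'
#' @param seed Master integer seed; every generator derives a named
#'   substream from it.
#' @param n_genes Number of genes in the expression time course.
#' @param class_proportions Named fractions per kinetic class; must sum to 1.
#'   Recognised classes are `fast_repressed`, `slow_repressed`, `activated`,
#'   `slow_activated` and `non_de`.
#' @param t_half_by_class Named half-maximal response times (hours) for the
#'   responsive classes.
#' @param timepoints Ordered sampling times in hours, starting at 0.
#' @param n_replicates Replicates per timepoint.
#' @param nb_dispersion Shared negative-binomial dispersion (variance
#'   `m + dispersion * m^2`); 0 gives noise-free rounded means.
#' @param response_floor Fraction of baseline expression remaining after
#'   full repression (mirrored as the fold gain of activated genes).
#' @param base_meanlog,base_sdlog Log-normal baseline expression parameters.
#' @param chrom,genome_length Toy chromosome name and length (bp).
#' @param n_peaks Target total number of accessibility peaks.
#' @param n_reg_genes Number of genes on the toy chromosome used for the
#'   regulatory-element analyses.
#' @param peak_width Range (bp) of peak widths.
#' @param peak_timepoints Accessibility/acetylation sampling times (hours).
#' @param motif_rate Motifs per 100 bp: Poisson rates for peaks near
#'   fast-repressed genes (`near_fast`) and elsewhere (`background`).
#' @param motif_density_effect Log-odds of accessibility loss per unit motif
#'   density (motifs/100 bp).
#' @param baseline_logodds Intercept of the loss logistic; `-Inf` yields a
#'   null simulation with no true changes.
#' @param frac_increased Probability that a non-decreased, non-CTCF peak
#'   truly gains accessibility.
#' @param enhancer_speedup Multiplier on the signal-loss rate at enhancers
#'   relative to promoters.
#' @param peak_depth,acetyl_depth Mean baseline counts for accessibility and
#'   H3K27ac.
#' @param loss_fold Full fold change of truly changed peaks.
#' @param peak_t_half Half-time (hours) of promoter signal loss.
#' @param enhancers_per_gene Mean enhancer counts near fast-repressed genes
#'   and near all other genes.
#' @param se_fraction_fast Probability that a fast-repressed gene carries a
#'   high-acetylation (super-enhancer-like) enhancer cluster.
#' @param se_signal_boost Acetylation multiplier at those clusters.
#' @param ctcf_fraction Fraction of background peaks annotated as CTCF
#'   sites (never truly changed).
#' @param n_contexts Number of activity contexts for enhancer-gene linking.
#' @param telegraph_params_by_condition Named list of [telegraph_params()]
#'   for the `uninduced` and `induced` conditions.
#' @param n_cells Cells per condition in the FISH simulation.
#' @return A validated `sim_config` object (named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 200)
#' cfg$t_half_by_class
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       class_proportions = c(
                         fast_repressed = 0.1, slow_repressed = 0.1,
                         activated = 0.1, slow_activated = 0.1,
                         non_de = 0.6
                       ),
                       t_half_by_class = c(
                         fast_repressed = 0.75, slow_repressed = 12,
                         activated = 3, slow_activated = 14.5
                       ),
                       timepoints = c(0, 0.5, 1, 2, 6, 12, 24),
                       n_replicates = 2L,
                       nb_dispersion = 0.05,
                       response_floor = 0.125,
                       base_meanlog = log(500),
                       base_sdlog = 1,
                       chrom = "chrS",
                       genome_length = 1e8,
                       n_peaks = 6000L,
                       n_reg_genes = 1500L,
                       peak_width = c(200L, 800L),
                       peak_timepoints = c(0, 0.5, 1, 2),
                       motif_rate = c(near_fast = 2.2, background = 0.35),
                       motif_density_effect = 1.5,
                       baseline_logodds = -2,
                       frac_increased = 0.05,
                       enhancer_speedup = 2,
                       peak_depth = 500,
                       acetyl_depth = 300,
                       loss_fold = 4,
                       peak_t_half = 1,
                       enhancers_per_gene = c(fast = 4, other = 2),
                       se_fraction_fast = 0.25,
                       se_signal_boost = 8,
                       ctcf_fraction = 0.15,
                       n_contexts = 8L,
                       telegraph_params_by_condition = list(
                         uninduced = telegraph_params(k_on = 1, k_off = 4),
                         induced = telegraph_params(k_on = 0.5, k_off = 4)
                       ),
                       n_cells = 700L) {
  known <- c(
    "fast_repressed", "slow_repressed", "activated", "slow_activated",
    "non_de"
  )
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% known)) {
    abort(paste(
      "unknown kinetic class; recognised classes:",
      paste(known, collapse = ", ")
    ))
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    abort("`class_proportions` must sum to 1")
  }
  if (any(diff(timepoints) <= 0) || timepoints[1] != 0) {
    abort("`timepoints` must be strictly increasing and start at 0")
  }
  responsive <- setdiff(names(class_proportions), "non_de")
  if (!all(responsive %in% names(t_half_by_class))) {
    abort("every responsive class needs an entry in `t_half_by_class`")
  }
  check_positive(t_half_by_class, "t_half_by_class")
  check_non_negative(nb_dispersion, "nb_dispersion")
  if (response_floor <= 0 || response_floor >= 1) {
    abort("`response_floor` must lie in (0, 1)")
  }
  check_positive(c(genome_length, peak_width, peak_depth, acetyl_depth,
                   loss_fold, peak_t_half, enhancer_speedup), "peak geometry")
  stopifnot(
    n_replicates >= 1, n_genes >= 1, n_peaks >= 1, n_cells >= 1,
    n_contexts >= 2, is.list(telegraph_params_by_condition)
  )
  for (p in telegraph_params_by_condition) {
    stopifnot(inherits(p, "telegraph_params"))
  }
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      class_proportions = class_proportions,
      t_half_by_class = t_half_by_class,
      timepoints = timepoints, n_replicates = as.integer(n_replicates),
      nb_dispersion = nb_dispersion, response_floor = response_floor,
      base_meanlog = base_meanlog, base_sdlog = base_sdlog,
      chrom = chrom, genome_length = genome_length,
      n_peaks = as.integer(n_peaks), n_reg_genes = as.integer(n_reg_genes),
      peak_width = peak_width, peak_timepoints = peak_timepoints,
      motif_rate = motif_rate,
      motif_density_effect = motif_density_effect,
      baseline_logodds = baseline_logodds,
      frac_increased = frac_increased,
      enhancer_speedup = enhancer_speedup,
      peak_depth = peak_depth, acetyl_depth = acetyl_depth,
      loss_fold = loss_fold, peak_t_half = peak_t_half,
      enhancers_per_gene = enhancers_per_gene,
      se_fraction_fast = se_fraction_fast,
      se_signal_boost = se_signal_boost,
      ctcf_fraction = ctcf_fraction,
      n_contexts = as.integer(n_contexts),
      telegraph_params_by_condition = telegraph_params_by_condition,
      n_cells = as.integer(n_cells)
    ),
    class = "sim_config"
  )
}

# Largest-remainder apportionment of n items to named fractions; totals are
# conserved exactly.
apportion_classes <- function(proportions, n) {
  raw <- proportions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(proportions))
}

#' Noise-free mean expression trajectory of a kinetic class
#'
#' Repressed classes decay exponentially from baseline towards
#' `base * floor`; activated classes rise symmetrically towards
#' `base / floor`. The time constant is chosen so that the min-max scaled
#' trajectory crosses 0.5 exactly at `t_half`.
#'
#' @param base Baseline expression (positive).
#' @param class Kinetic class name.
#' @param t_half Half-maximal response time (hours); ignored for `non_de`.
#' @param timepoints Hours at which to evaluate the mean.
#' @param response_floor Remaining fraction after full repression.
#' @return Numeric vector of means, one per timepoint.
#' @export
#' @examples
#' mean_trajectory(100, "fast_repressed", 0.75, c(0, 0.75, 24))
mean_trajectory <- function(base, class, t_half, timepoints,
                            response_floor = 0.125) {
  check_positive(base, "base")
  decay <- 2^(-timepoints / t_half)
  if (grepl("repressed", class)) {
    base * (response_floor + (1 - response_floor) * decay)
  } else if (grepl("activated", class)) {
    fold <- 1 / response_floor
    base * (1 + (fold - 1) * (1 - decay))
  } else if (class == "non_de") {
    rep(base, length(timepoints))
  } else {
    abort(paste0("unknown kinetic class: ", class))
  }
}

# NB draw with the package's dispersion convention; dispersion 0 returns the
# rounded mean (noise-free limit).
rnbinom_disp <- function(n, mu, dispersion) {
  if (dispersion == 0) {
    return(round(mu))
  }
  rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a nascent-transcription count time course with known classes
#'
#' Draws per-gene negative-binomial counts around class-specific exponential
#' trajectories (see [mean_trajectory()]). Baseline expression is log-normal;
#' classes and their half-times come from the configuration.
#'
#' @param config A [sim_config()].
#' @return A list of class `tc_sim`:
#'   * `counts` — tibble `(gene, timepoint, replicate, count)`;
#'   * `truth`  — tibble `(gene, class, base_mean, t_half)`.
#' @export
#' @examples
#' sim <- simulate_timecourse(sim_config(seed = 1, n_genes = 50))
#' dplyr::count(sim$truth, class)
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_by_class <- apportion_classes(config$class_proportions, config$n_genes)
  classes <- rep(names(n_by_class), n_by_class)
  with_seed(substream_seed(config$seed, "timecourse"), {
    base <- rlnorm(config$n_genes, config$base_meanlog, config$base_sdlog)
    truth <- tibble(
      gene = sprintf("g%05d", seq_len(config$n_genes)),
      class = classes,
      base_mean = base,
      t_half = unname(ifelse(
        classes == "non_de", NA_real_, config$t_half_by_class[classes]
      ))
    )
    tp <- config$timepoints
    # gene x timepoint mean matrix, built class-wise
    mu_mat <- matrix(0, config$n_genes, length(tp))
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      th <- if (cl == "non_de") 1 else config$t_half_by_class[[cl]]
      shape <- mean_trajectory(1, cl, th, tp, config$response_floor)
      mu_mat[idx, ] <- outer(base[idx], shape)
    }
    nrep <- config$n_replicates
    mu_long <- rep(t(mu_mat), each = nrep)  # gene-major, then tp, then rep
    counts <- tibble(
      gene = rep(truth$gene, each = length(tp) * nrep),
      timepoint = rep(rep(tp, each = nrep), config$n_genes),
      replicate = rep(seq_len(nrep), length(tp) * config$n_genes),
      count = rnbinom_disp(length(mu_long), mu_long, config$nb_dispersion)
    )
    structure(list(counts = counts, truth = truth), class = "tc_sim")
  })
}

#' Simulate an accessibility/acetylation peak landscape with known classes
#'
#' Builds a toy chromosome with regularly spaced genes of known kinetic
#' class, a promoter peak per gene, class-dependent numbers of enhancer
#' peaks in the +/-20 kb neighbourhood, and background/CTCF peaks in the
#' intergenic space. Each peak carries an embedded binding-motif count; the
#' probability that a peak truly loses accessibility is a logistic function
#' of its motif density, so that lost peaks are enriched for motifs exactly
#' as the downstream statistics should detect. Truly changed peaks decay (or
#' gain) signal over the early timepoints, with enhancers decaying
#' `enhancer_speedup`-fold faster than promoters. High-acetylation enhancer
#' clusters are planted preferentially near fast-repressed genes, and
#' TF-binding peaks are centred on truly decreased peaks. Context activity
#' matrices and a distance-decaying contact matrix support enhancer-gene
#' linking.
#'
#' @param config A [sim_config()].
#' @return A list of class `peak_sim` with tibbles `peaks`, `counts` (long,
#'   per assay/timepoint/replicate), `genes`, `h3k27ac_peaks`, `tf_peaks`,
#'   `activity`, `gene_activity` and `contacts`.
#' @export
simulate_peaks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "peaks"), {
    n_reg <- config$n_reg_genes
    spacing <- config$genome_length / n_reg
    if (spacing < 45000) {
      abort("genome too short for non-overlapping +/-20kb gene neighbourhoods")
    }
    # gene classes on the toy chromosome follow the expression-class
    # proportions (non-DE majority), so that "randomly sampled gene"
    # controls are not dominated by the enhancer-rich responsive classes
    reg_classes <- sample(rep(
      names(config$class_proportions),
      apportion_classes(config$class_proportions, n_reg)
    ))
    tss <- round((seq_len(n_reg) - 0.5) * spacing +
                   runif(n_reg, -spacing / 12, spacing / 12))
    genes <- tibble(
      gene = sprintf("rg%05d", seq_len(n_reg)),
      class = reg_classes,
      tss = as.integer(tss),
      strand = sample(c("+", "-"), n_reg, replace = TRUE),
      se_locus = reg_classes == "fast_repressed" &
        runif(n_reg) < config$se_fraction_fast
    )

    rand_width <- function(n) {
      as.integer(round(runif(n, config$peak_width[1], config$peak_width[2])))
    }

    # promoter peak at each TSS
    wp <- rand_width(n_reg)
    prom <- tibble(
      gene = genes$gene, gene_class = genes$class, se_locus = genes$se_locus,
      center = genes$tss, width = wp, element = "promoter",
      category = "promoter"
    )

    # enhancer peaks on a 1 kb slot grid within +/-20 kb of the TSS
    mean_enh <- ifelse(genes$class == "fast_repressed",
                       config$enhancers_per_gene[["fast"]],
                       config$enhancers_per_gene[["other"]])
    k_enh <- pmin(rpois(n_reg, mean_enh), 12L)
    slots <- c(-20:-2, 2:20)
    enh <- map(which(k_enh > 0), function(i) {
      off <- sample(slots, k_enh[i]) * 1000L +
        as.integer(round(runif(k_enh[i], -90, 90)))
      body_lo <- if (genes$strand[i] == "+") genes$tss[i] else genes$tss[i] - 10000
      body_hi <- body_lo + 10000
      ctr <- genes$tss[i] + off
      tibble(
        gene = genes$gene[i], gene_class = genes$class[i],
        se_locus = genes$se_locus[i],
        center = ctr, width = rand_width(k_enh[i]), element = "enhancer",
        category = ifelse(ctr >= body_lo & ctr <= body_hi,
                          "intragenic", "intergenic")
      )
    }) %>% list_rbind()

    # background peaks on a 5 kb grid outside gene neighbourhoods
    n_background <- max(config$n_peaks - nrow(prom) - nrow(enh), 0L)
    grid <- seq(2500, config$genome_length - 2500, by = 2500)
    near_gene <- overlaps_any(grid, grid + 1L, genes$tss - 22000,
                              genes$tss + 22000)
    free <- grid[!near_gene]
    if (n_background > length(free)) {
      abort("not enough intergenic space for the requested background peaks")
    }
    bg_ctr <- sort(sample(free, n_background))
    bg <- tibble(
      gene = NA_character_, gene_class = NA_character_, se_locus = FALSE,
      center = as.integer(bg_ctr), width = rand_width(n_background),
      element = "background",
      category = ifelse(runif(n_background) < config$ctcf_fraction,
                        "CTCF", "intergenic")
    )

    peaks <- bind_rows(prom, enh, bg) %>%
      mutate(
        start = as.integer(.data$center - .data$width %/% 2L),
        end = as.integer(.data$start + .data$width)
      ) %>%
      arrange(.data$start) %>%
      mutate(peak_id = sprintf("pk%05d", row_number()))
    if (any(peaks$start[-1] < peaks$end[-nrow(peaks)])) {
      abort("simulated peaks overlap beyond the configured tolerance")
    }

    # embedded motif counts -> logistic probability of true loss
    lam100 <- ifelse(
      !is.na(peaks$gene_class) & peaks$gene_class == "fast_repressed",
      config$motif_rate[["near_fast"]], config$motif_rate[["background"]]
    )
    motif_count <- rpois(nrow(peaks), lam100 * peaks$width / 100)
    density100 <- 100 * motif_count / peaks$width
    p_dec <- plogis(config$baseline_logodds +
                      config$motif_density_effect * density100)
    p_dec[peaks$category == "CTCF"] <- 0
    decreased <- runif(nrow(peaks)) < p_dec
    increased <- !decreased & peaks$category != "CTCF" &
      runif(nrow(peaks)) < config$frac_increased
    peaks <- peaks %>%
      mutate(
        chrom = config$chrom,
        motif_count = motif_count,
        motif_density = motif_count / .data$width,
        class_true = case_when(
          decreased ~ "decreased",
          increased ~ "increased",
          TRUE ~ "unchanged"
        )
      ) %>%
      select(
        "peak_id", "chrom", "start", "end", "width", "category", "element",
        "gene", "gene_class", "se_locus", "motif_count", "motif_density",
        "class_true"
      )

    # per-timepoint signal counts (accessibility for all peaks, H3K27ac for
    # promoter/enhancer peaks); enhancers lose signal faster
    tau <- ifelse(peaks$element == "enhancer",
                  config$peak_t_half / config$enhancer_speedup,
                  config$peak_t_half)
    tp <- config$peak_timepoints
    nrep <- config$n_replicates
    floorf <- 1 / config$loss_fold
    depth_atac <- rlnorm(nrow(peaks), log(config$peak_depth), 0.4)
    depth_ac <- rlnorm(nrow(peaks), log(config$acetyl_depth), 0.4) *
      ifelse(peaks$se_locus & peaks$element == "enhancer",
             config$se_signal_boost, 1)

    # peak x timepoint trajectory shape (1 = stationary)
    decay <- outer(1 / tau, tp, function(inv_tau, t) 2^(-t * inv_tau))
    shape <- matrix(1, nrow(peaks), length(tp))
    is_dec <- peaks$class_true == "decreased"
    is_inc <- peaks$class_true == "increased"
    shape[is_dec, ] <- floorf + (1 - floorf) * decay[is_dec, ]
    shape[is_inc, ] <- 1 + (config$loss_fold - 1) * (1 - decay[is_inc, ])

    long_counts <- function(idx, assay, depth) {
      mu <- rep(t(shape[idx, , drop = FALSE] * depth[idx]), each = nrep)
      tibble(
        peak_id = rep(peaks$peak_id[idx], each = length(tp) * nrep),
        assay = assay,
        timepoint = rep(rep(tp, each = nrep), length(idx)),
        replicate = rep(seq_len(nrep), length(tp) * length(idx)),
        count = rnbinom_disp(length(mu), mu, config$nb_dispersion)
      )
    }
    marked_idx <- which(peaks$element %in% c("promoter", "enhancer"))
    counts <- bind_rows(
      long_counts(seq_len(nrow(peaks)), "atac", depth_atac),
      long_counts(marked_idx, "h3k27ac", depth_ac)
    )

    # H3K27ac peak intervals: widened footprints of promoter/enhancer peaks
    h3k <- peaks %>%
      filter(.data$element %in% c("promoter", "enhancer")) %>%
      mutate(start = pmax(.data$start - 200L, 0L), end = .data$end + 200L) %>%
      select("chrom", "start", "end")

    # TF-binding peaks: summits centred on truly decreased peaks, uniform
    # within a sample of other peaks
    dec_idx <- which(peaks$class_true == "decreased" & runif(nrow(peaks)) < 0.9)
    oth_pool <- which(peaks$class_true != "decreased")
    oth_idx <- sort(sample(oth_pool, max(1L, round(0.1 * length(oth_pool)))))
    mid <- interval_midpoint(peaks$start, peaks$end)
    summit_dec <- mid[dec_idx] + round(rnorm(length(dec_idx), 0, 15))
    summit_oth <- as.integer(round(runif(
      length(oth_idx), peaks$start[oth_idx] + 1, peaks$end[oth_idx] - 1
    )))
    tf_peaks <- tibble(
      chrom = config$chrom,
      summit = as.integer(c(summit_dec, summit_oth)),
      start = as.integer(c(summit_dec, summit_oth)) - 150L,
      end = as.integer(c(summit_dec, summit_oth)) + 150L
    ) %>% arrange(.data$start)

    # context activity + contact matrix for enhancer-gene linking
    nc <- config$n_contexts
    ctx <- sprintf("ctx_%02d", seq_len(nc))
    g_act <- matrix(rnorm(n_reg * nc), n_reg, nc,
                    dimnames = list(genes$gene, ctx))
    enh_peaks <- peaks %>% filter(.data$element == "enhancer")
    true_pair <- runif(nrow(enh_peaks)) < 0.7
    e_act <- matrix(rnorm(nrow(enh_peaks) * nc, 0, 1), nrow(enh_peaks), nc)
    e_act[true_pair, ] <- 0.8 * g_act[enh_peaks$gene[true_pair], ] +
      matrix(rnorm(sum(true_pair) * nc, 0, 0.4), sum(true_pair), nc)
    activity <- as_tibble(e_act, .name_repair = ~ctx) %>%
      mutate(element_id = enh_peaks$peak_id, .before = 1)
    gene_activity <- as_tibble(g_act, .name_repair = ~ctx) %>%
      mutate(gene = genes$gene, .before = 1)

    e_mid <- interval_midpoint(enh_peaks$start, enh_peaks$end)
    contacts <- map(seq_len(nrow(enh_peaks)), function(i) {
      d <- abs(genes$tss - e_mid[i])
      cand <- which(d <= 5e5)
      if (length(cand) == 0) return(NULL)
      boost <- ifelse(genes$gene[cand] == enh_peaks$gene[i] & true_pair[i],
                      5, 1)
      tibble(
        element_id = enh_peaks$peak_id[i],
        gene = genes$gene[cand],
        contact = exp(-d[cand] / 2e5) * boost * runif(length(cand), 0.8, 1.2)
      )
    }) %>% list_rbind()

    structure(
      list(
        peaks = peaks, counts = counts, genes = genes,
        h3k27ac_peaks = h3k, tf_peaks = tf_peaks,
        activity = activity, gene_activity = gene_activity,
        contacts = contacts,
        truth = list(true_pair = setNames(true_pair, enh_peaks$peak_id))
      ),
      class = "peak_sim"
    )
  })
}

#' Simulate single-molecule FISH burst tables for two conditions
#'
#' Each cell contributes two alleles; an allele is bursting with the
#' telegraph stationary probability `k_on / (k_on + k_off)` of its
#' condition. Bursting alleles receive spot features (maximum intensity,
#' mean radius) drawn around the configured means; non-bursting alleles have
#' missing features.
#'
#' @param params0,params1 [telegraph_params()] for the two conditions
#'   (e.g. uninduced and induced).
#' @param n_cells Cells per condition.
#' @param seed Integer seed.
#' @return A list of class `fish_sim` with tibbles `condition0` and
#'   `condition1`, columns `(cell_id, allele, burst, Intensity_MaxIntensity,
#'   AreaShape_MeanRadius)`.
#' @export
#' @examples
#' fs <- simulate_fish(telegraph_params(1, 4), telegraph_params(0.5, 4),
#'                     n_cells = 100, seed = 1)
#' mean(fs$condition0$burst)
simulate_fish <- function(params0, params1, n_cells, seed) {
  stopifnot(
    inherits(params0, "telegraph_params"),
    inherits(params1, "telegraph_params"), n_cells > 0
  )
  one <- function(p, cond_seed) {
    with_seed(cond_seed, {
      n_alleles <- 2L * n_cells
      pr <- telegraph_stationary_fraction(p$k_on, p$k_off)
      burst <- runif(n_alleles) < pr
      inten <- ifelse(burst,
                      pmax(rnorm(n_alleles, p$burst_intensity_mean, p$noise_sd),
                           0.01),
                      NA_real_)
      rad <- ifelse(burst,
                    pmax(rnorm(n_alleles, p$burst_radius_mean,
                               p$noise_sd / 4), 0.01),
                    NA_real_)
      tibble(
        cell_id = rep(seq_len(n_cells), each = 2L),
        allele = rep(1:2, n_cells),
        burst = burst,
        Intensity_MaxIntensity = inten,
        AreaShape_MeanRadius = rad
      )
    })
  }
  structure(
    list(
      condition0 = one(params0, substream_seed(seed, "fish0")),
      condition1 = one(params1, substream_seed(seed, "fish1"))
    ),
    class = "fish_sim"
  )
}

#' Long-run ON-state occupancy of a simulated telegraph trajectory
#'
#' Alternates exponential ON/OFF sojourns (a two-state Gillespie path) and
#' returns the fraction of time spent ON. Serves as an independent check of
#' the closed-form stationary probability.
#'
#' @param params A [telegraph_params()] with both rates positive.
#' @param n_switches Number of state switches to simulate.
#' @param seed Integer seed.
#' @return Fraction of elapsed time in the ON state.
#' @export
telegraph_trajectory <- function(params, n_switches = 10000, seed = 1) {
  stopifnot(inherits(params, "telegraph_params"))
  check_positive(c(params$k_on, params$k_off), "k_on/k_off")
  with_seed(seed, {
    n_pairs <- ceiling(n_switches / 2)
    t_off <- rexp(n_pairs, params$k_on)   # waiting time to switch ON
    t_on <- rexp(n_pairs, params$k_off)   # waiting time to switch OFF
    sum(t_on) / (sum(t_on) + sum(t_off))
  })
}
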