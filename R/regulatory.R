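# Regulatory-element analysis: promoter/enhancer classification of
# accessible sites, super-enhancer calling by stitch-and-elbow, enhancer
# association statistics per kinetic gene class, and enhancer-gene linking
# by activity correlation plus contact frequency.
#
# Window membership is closed on both sides: [TSS - w, TSS + w].

#' Classify accessible sites as active promoters or enhancers
#'
#' An accessible site overlapping an H3K27ac peak is an active element:
#' `active_promoter` when it lies within `promoter_window` bp of any TSS,
#' `active_enhancer` when distal. Sites without H3K27ac overlap remain
#' unclassified (`NA`) regardless of position.
#'
#' @param atac_peaks Tibble `(peak_id, start, end, ...)` of accessible sites.
#' @param h3k27ac_peaks Tibble `(start, end)` of acetylation peaks.
#' @param genes Tibble with a `tss` column.
#' @param promoter_window Half-width (bp) of the promoter window around the
#'   TSS (default 1000).
#' @return `atac_peaks` with a `kind` column added.
#' @export
classify_elements <- function(atac_peaks, h3k27ac_peaks, genes,
                              promoter_window = 1000) {
  if (!"tss" %in% names(genes)) {
    abort("`genes` must carry a `tss` column")
  }
  marked <- overlaps_any(atac_peaks$start, atac_peaks$end,
                         h3k27ac_peaks$start, h3k27ac_peaks$end)
  # closed promoter windows: peak overlaps [tss - w, tss + w]
  near_tss <- overlaps_any(atac_peaks$start, atac_peaks$end,
                           genes$tss - promoter_window,
                           genes$tss + promoter_window + 1L)
  atac_peaks %>%
    mutate(kind = case_when(
      marked & near_tss ~ "active_promoter",
      marked ~ "active_enhancer",
      TRUE ~ NA_character_
    ))
}

#' Call super-enhancers by stitching and rank-elbow cutoff
#'
#' Enhancers within `stitch_distance` bp of each other are merged; stitched
#' regions are ranked by total signal and the rank-signal curve is scaled to
#' the unit square. The cutoff sits where the tangent of the (convex)
#' curve reaches slope 1 — located, robustly to bin-to-bin noise, as the
#' point minimising `y - x`, i.e. where a line of slope 1 touches the curve
#' from below. Regions above the cutoff are super-enhancers. When all
#' signals are equal (or the curve never dips below the diagonal) the elbow
#' is undefined and no super-enhancers are called.
#'
#' @param enhancers Tibble `(start, end, signal)` of enhancer elements with
#'   per-element total acetylation signal; at least 3 rows.
#' @param stitch_distance Maximum gap (bp) merged across (default 12500).
#' @return A list of class `se_call`:
#'   * `regions` — stitched regions with `start`, `end`, `n_enhancers`,
#'     `total_signal`, `rank` (ascending by signal) and `is_super`;
#'   * `cutoff_signal` — signal at the elbow (`NA` when undefined).
#' @export
call_super_enhancers <- function(enhancers, stitch_distance = 12500) {
  stopifnot(all(c("start", "end", "signal") %in% names(enhancers)))
  if (nrow(enhancers) < 3) {
    abort("need at least 3 enhancers to call super-enhancers")
  }
  e <- arrange(enhancers, .data$start)
  grp <- cumsum(c(1, as.integer(
    e$start[-1] - cummax(e$end[-nrow(e)]) > stitch_distance
  )))
  regions <- e %>%
    mutate(.grp = grp) %>%
    group_by(.data$.grp) %>%
    summarise(
      start = min(.data$start), end = max(.data$end),
      n_enhancers = n(), total_signal = sum(.data$signal),
      .groups = "drop"
    ) %>%
    select(-".grp") %>%
    arrange(.data$total_signal) %>%
    mutate(rank = row_number())

  n <- nrow(regions)
  sig <- regions$total_signal
  if (max(sig) - min(sig) <= 0 || n < 2) {
    regions$is_super <- FALSE
    return(structure(list(regions = regions, cutoff_signal = NA_real_),
                     class = "se_call"))
  }
  x <- (regions$rank - 1) / (n - 1)
  y <- (sig - min(sig)) / (max(sig) - min(sig))
  gap <- y - x
  if (min(gap) >= -1e-9) {       # curve never below the diagonal: no elbow
    regions$is_super <- FALSE
    cutoff <- NA_real_
  } else {
    cut_idx <- which.min(gap)    # tangent point of the slope-1 line
    cutoff <- sig[cut_idx]
    regions$is_super <- regions$rank > cut_idx
  }
  structure(list(regions = regions, cutoff_signal = cutoff),
            class = "se_call")
}

# Elements (by midpoint) within the closed window [tss - w, tss + w].
midpoint_in_window <- function(mid, tss, window) {
  abs(mid - tss) <= window
}

#' Enhancer density around TSSs by kinetic gene class
#'
#' Counts, for each gene, the accessible active-enhancer sites whose
#' midpoint lies within the closed window `[TSS - window, TSS + window]`,
#' and compares the fast-repressed class against every other class with
#' two-sided Wilcoxon rank-sum tests, Bonferroni-corrected.
#'
#' @param genes Tibble `(gene, class, tss)`; every class non-empty.
#' @param elements Element table from [classify_elements()] (rows with
#'   `kind == "active_enhancer"` are used).
#' @param window Half-window in bp (default 20000).
#' @param reference_class Class compared against the others.
#' @return A list with `counts` (per-gene enhancer counts) and `tests`
#'   (per-class `p_value`, `p_adjusted` vs the reference class).
#' @export
enhancer_density_by_gene_class <- function(genes, elements, window = 20000,
                                           reference_class =
                                             "fast_repressed") {
  if (any(table(genes$class) == 0) || nrow(genes) == 0) {
    abort("every gene class must be non-empty")
  }
  enh <- filter(elements, .data$kind == "active_enhancer")
  mid <- interval_midpoint(enh$start, enh$end)
  counts <- genes %>%
    mutate(n_enhancers = map_int(.data$tss, function(t0) {
      sum(midpoint_in_window(mid, t0, window))
    }))
  others <- setdiff(unique(genes$class), reference_class)
  ref_counts <- counts$n_enhancers[counts$class == reference_class]
  tests <- map(others, function(cl) {
    wt <- suppressWarnings(wilcox.test(
      ref_counts, counts$n_enhancers[counts$class == cl],
      alternative = "two.sided"
    ))
    tibble(class = cl, statistic = unname(wt$statistic),
           p_value = wt$p.value)
  }) %>% list_rbind()
  tests$p_adjusted <- pmin(tests$p_value * nrow(tests), 1)  # Bonferroni
  list(counts = counts, tests = tests)
}

#' Super-enhancer association by kinetic gene class
#'
#' Fraction of genes per class with at least one super-enhancer overlapping
#' the closed window `[TSS - window, TSS + window]`, plus a seeded
#' randomly-sampled control class of the same size as the reference class.
#'
#' @param genes Tibble `(gene, class, tss)`.
#' @param se_call A [call_super_enhancers()] result (or a tibble of regions
#'   with `start`, `end`, `is_super`).
#' @param window Half-window in bp (default 50000).
#' @param seed Seed for the random control sample.
#' @param reference_class Class whose size the control matches.
#' @return Tibble `(class, n_genes, n_with_se, fraction)` including a
#'   `random` control row.
#' @export
se_association <- function(genes, se_call, window = 50000, seed = 1,
                           reference_class = "fast_repressed") {
  regions <- if (inherits(se_call, "se_call")) se_call$regions else se_call
  ses <- filter(regions, .data$is_super)
  has_se <- if (nrow(ses) == 0) {
    rep(FALSE, nrow(genes))
  } else {
    overlaps_any(genes$tss - window, genes$tss + window + 1L,
                 ses$start, ses$end)
  }
  n_ref <- sum(genes$class == reference_class)
  ctrl_idx <- with_seed(substream_seed(seed, "se_control"),
                        sample(nrow(genes), min(n_ref, nrow(genes))))
  aug <- bind_rows(
    tibble(class = genes$class, has_se = has_se),
    tibble(class = "random", has_se = has_se[ctrl_idx])
  )
  aug %>%
    group_by(.data$class) %>%
    summarise(
      n_genes = n(), n_with_se = sum(.data$has_se),
      fraction = mean(.data$has_se), .groups = "drop"
    )
}

#' Link enhancers to genes by activity correlation and contact frequency
#'
#' For every candidate enhancer-gene pair within `max_distance` bp, computes
#' the Pearson correlation of their activities across shared contexts; a
#' pair is linked when the correlation reaches `r_min` and the contact
#' frequency reaches `c_min` (default: the 95th percentile of contacts over
#' all candidate pairs). Zero-variance activity vectors are skipped and
#' flagged.
#'
#' @param activity Tibble: `element_id` plus one column per context.
#' @param gene_activity Tibble: `gene` plus the same context columns.
#' @param contacts Long tibble `(element_id, gene, contact)`.
#' @param elements Tibble `(peak_id, start, end)` giving enhancer positions.
#' @param genes Tibble `(gene, class, tss)`.
#' @param r_min Minimum Pearson correlation (default 0.5).
#' @param c_min Minimum contact frequency; `NULL` uses the background 95th
#'   percentile.
#' @param max_distance Candidate radius in bp (default 5e5).
#' @return A list of class `enhancer_links`:
#'   * `links` — per-pair tibble `(element_id, gene, distance, correlation,
#'     contact, linked, flagged)`;
#'   * `by_class` — per-gene-class mean and total link counts;
#'   * `c_min` — the contact threshold used.
#' @export
link_enhancers <- function(activity, gene_activity, contacts, elements,
                           genes, r_min = 0.5, c_min = NULL,
                           max_distance = 5e5) {
  ctx <- setdiff(names(activity), "element_id")
  if (!identical(sort(ctx), sort(setdiff(names(gene_activity), "gene")))) {
    abort("`activity` and `gene_activity` must share context columns")
  }
  if (length(ctx) < 5) {
    abort("at least 5 shared contexts are required for correlation")
  }
  el <- elements %>%
    filter(.data$peak_id %in% activity$element_id) %>%
    mutate(mid = interval_midpoint(.data$start, .data$end))
  e_mat <- as.matrix(activity[, ctx])
  rownames(e_mat) <- activity$element_id
  g_mat <- as.matrix(gene_activity[, ctx])
  rownames(g_mat) <- gene_activity$gene

  cand <- map(seq_len(nrow(el)), function(i) {
    d <- abs(genes$tss - el$mid[i])
    j <- which(d <= max_distance)
    if (length(j) == 0) return(NULL)
    tibble(element_id = el$peak_id[i], gene = genes$gene[j],
           distance = d[j])
  }) %>% list_rbind()
  if (is.null(cand) || nrow(cand) == 0) {
    abort("no candidate enhancer-gene pairs within `max_distance`")
  }
  cand <- left_join(cand, contacts, by = c("element_id", "gene")) %>%
    mutate(contact = dplyr::coalesce(.data$contact, 0))
  if (is.null(c_min)) {
    c_min <- unname(quantile(cand$contact, 0.95))
  }
  ev <- e_mat[cand$element_id, , drop = FALSE]
  gv <- g_mat[cand$gene, , drop = FALSE]
  sd_e <- apply(ev, 1, sd)
  sd_g <- apply(gv, 1, sd)
  flagged <- sd_e == 0 | sd_g == 0
  corr <- rep(NA_real_, nrow(cand))
  ok <- !flagged
  if (any(ok)) {
    corr[ok] <- map_dbl(which(ok), function(i) cor(ev[i, ], gv[i, ]))
  }
  links <- cand %>%
    mutate(
      correlation = corr, flagged = flagged,
      linked = !flagged & corr >= r_min & .data$contact >= c_min
    )
  by_class <- links %>%
    group_by(.data$gene) %>%
    summarise(n_links = sum(.data$linked), .groups = "drop") %>%
    left_join(select(genes, "gene", "class"), by = "gene") %>%
    group_by(.data$class) %>%
    summarise(
      n_genes = n(), mean_links = mean(.data$n_links),
      total_links = sum(.data$n_links), .groups = "drop"
    )
  structure(list(links = links, by_class = by_class, c_min = c_min),
            class = "enhancer_links")
}

#' Fractions of proximal elements losing or gaining signal, by gene class
#'
#' Runs the negative-binomial test on per-element acetylation counts, then
#' reports for each kinetic gene class the fraction of elements whose
#' midpoint lies within the closed window around a class gene's TSS and
#' that significantly lose (`padj < alpha`, fold change <= 1/`min_fc`) or
#' gain (`padj < alpha`, fold change >= `min_fc`) signal, together with a
#' seeded random-gene control of the reference-class size.
#'
#' @param genes Tibble `(gene, class, tss)`.
#' @param elements Element table (rows with non-`NA` `kind` are used).
#' @param element_counts Long tibble `(peak_id, timepoint, replicate,
#'   count)` of acetylation counts for the elements.
#' @param t_ref,t Timepoints compared (hours).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param min_fc Minimum fold change (default 1.5).
#' @param window Half-window in bp (default 20000).
#' @param seed Seed for the random-gene control.
#' @param reference_class Class whose size the control matches.
#' @return Tibble `(class, n_elements, loss_fraction, gain_fraction)`
#'   including a `random` control row.
#' @export
change_fraction_by_class <- function(genes, elements, element_counts,
                                     t_ref, t, alpha = 0.01, min_fc = 1.5,
                                     window = 20000, seed = 1,
                                     reference_class = "fast_repressed") {
  if (nrow(genes) == 0 || any(table(genes$class) == 0)) {
    abort("every gene class must be non-empty")
  }
  el <- filter(elements, !is.na(.data$kind))
  sub_counts <- filter(element_counts, .data$peak_id %in% el$peak_id)
  norm <- if ("norm_count" %in% names(sub_counts)) {
    sub_counts
  } else {
    normalize_counts(sub_counts, id_col = "peak_id")
  }
  stats <- nb_wald_test(norm, "peak_id", t_ref, t) %>%
    mutate(
      loss = .data$p_adjusted < alpha &
        .data$log2_fold_change <= -log2(min_fc),
      gain = .data$p_adjusted < alpha &
        .data$log2_fold_change >= log2(min_fc)
    )
  el <- el %>%
    mutate(mid = interval_midpoint(.data$start, .data$end)) %>%
    left_join(select(stats, "peak_id", "loss", "gain"), by = "peak_id")

  n_ref <- sum(genes$class == reference_class)
  ctrl <- with_seed(substream_seed(seed, "change_control"),
                    genes[sample(nrow(genes), min(n_ref, nrow(genes))), ])
  class_sets <- c(
    split(genes, genes$class),
    list(random = ctrl)
  )
  imap(class_sets, function(gs, cl) {
    near <- map(gs$tss, function(t0) {
      which(midpoint_in_window(el$mid, t0, window))
    }) %>% unlist() %>% unique()
    sub <- el[near, , drop = FALSE]
    tibble(
      class = cl, n_elements = nrow(sub),
      loss_fraction = if (nrow(sub)) mean(sub$loss) else NA_real_,
      gain_fraction = if (nrow(sub)) mean(sub$gain) else NA_real_
    )
  }) %>% list_rbind()
}
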