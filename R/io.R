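# File formats and the end-to-end pipeline driver.

#' Read a BED3/BED6 file
#'
#' Parses 0-based half-open intervals, tolerating and skipping `track`,
#' `browser` and `#` comment lines. Malformed lines (fewer than 3 fields,
#' non-integer coordinates, `start >= end`) raise an error naming the line
#' number. The result is sorted by `(chrom, start)`.
#'
#' @param path Path to a BED file.
#' @return Tibble `(chrom, start, end, name, score, strand)`; the last
#'   three columns are `NA` for BED3 input.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0) {
    abort("no interval lines found")
  }
  parsed <- map(rows, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(paste0("line ", i, ": expected at least 3 tab-separated fields"))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      abort(paste0("line ", i, ": non-integer coordinates"))
    }
    if (start >= end) {
      abort(paste0("line ", i, ": start (", start, ") must be < end (",
                   end, ")"))
    }
    tibble(
      chrom = f[1], start = start, end = end,
      name = if (length(f) >= 4) f[4] else NA_character_,
      score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5]))
              else NA_real_,
      strand = if (length(f) >= 6) f[6] else NA_character_
    )
  }) %>% list_rbind()
  arrange(parsed, .data$chrom, .data$start)
}

#' Write intervals as BED6
#'
#' @param df Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- tibble(
    chrom = df$chrom, start = df$start, end = df$end,
    name = df$name %||% ".",
    score = df$score %||% 0,
    strand = df$strand %||% "."
  )
  out$name[is.na(out$name)] <- "."
  out$score[is.na(out$score)] <- 0
  out$strand[is.na(out$strand)] <- "."
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the simulation configuration, analysis thresholds and stage
#' toggles for [run_pipeline()]. All randomness derives from the single
#' `sim$seed` via named substreams.
#'
#' @param sim A [sim_config()].
#' @param stages Character vector of enabled stages, a subset of
#'   `c("kinetics", "accessibility", "regulatory", "bursting")`.
#' @param alpha Adjusted-p threshold shared by the differential tests.
#' @param min_abs_log2fc DE fold-change threshold (log2).
#' @param min_fc Acetylation change fold threshold.
#' @param de_timepoint Timepoint (hours) tested against 0 for DE calling.
#' @param peak_timepoint Timepoint (hours) tested against 0 for peaks.
#' @param k Number of K-means clusters.
#' @param promoter_window,density_window,se_window Windows in bp.
#' @param r_min Minimum linking correlation.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("kinetics", "accessibility",
                                       "regulatory", "bursting"),
                            alpha = 0.01, min_abs_log2fc = 1, min_fc = 1.5,
                            de_timepoint = NULL, peak_timepoint = NULL,
                            k = 5, promoter_window = 1000,
                            density_window = 20000, se_window = 50000,
                            r_min = 0.5) {
  stopifnot(inherits(sim, "sim_config"))
  bad <- setdiff(stages, c("kinetics", "accessibility", "regulatory",
                           "bursting"))
  if (length(bad)) {
    abort(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  }
  stopifnot(alpha > 0, alpha < 1, min_abs_log2fc >= 0, min_fc >= 1,
            k >= 2, promoter_window > 0, density_window > 0, se_window > 0)
  structure(
    list(
      sim = sim, stages = stages, alpha = alpha,
      min_abs_log2fc = min_abs_log2fc, min_fc = min_fc,
      de_timepoint = de_timepoint %||% max(sim$timepoints),
      peak_timepoint = peak_timepoint %||% max(sim$peak_timepoints),
      k = k, promoter_window = promoter_window,
      density_window = density_window, se_window = se_window,
      r_min = r_min
    ),
    class = "pipeline_config"
  )
}

# Stage-stamped TSV writer: every output carries the producing stage and
# the configuration hash in a header comment.
write_stage_tsv <- function(df, path, stage, cfg_hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# stage=", stage, " config_hash=", cfg_hash), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Run the full synthetic-to-report pipeline
#'
#' Chains simulation, kinetic analysis, accessibility classification,
#' regulatory-element statistics and burst analysis; writes per-stage TSV
#' tables, a JSON summary report and a manifest to `out_dir`. Re-running
#' with the same configuration produces byte-identical outputs. Disabled
#' stages are omitted from the report; a stage failure aborts with the
#' stage name and cause.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The report as a named list, invisibly; files in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config)
  report <- list(seed = config$sim$seed, config_hash = cfg_hash)
  manifest <- list(
    tool = "tfresponse", config_hash = cfg_hash, seed = config$sim$seed,
    thresholds = list(
      alpha = config$alpha, min_abs_log2fc = config$min_abs_log2fc,
      min_fc = config$min_fc, r_min = config$r_min
    ),
    stages = list()
  )
  run_stage <- function(name, fn) {
    if (!name %in% c("simulate", config$stages)) {
      manifest$stages[[name]] <<- list(status = "disabled")
      return(NULL)
    }
    out <- tryCatch(fn(), error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    manifest$stages[[name]] <<- c(list(status = "ok"), out$log)
    out$value
  }
  stamp <- function(df, file, stage) {
    write_stage_tsv(df, file.path(out_dir, file), stage, cfg_hash)
  }

  sim_tc <- NULL
  sim_pk <- NULL
  run_stage("simulate", function() {
    sim_tc <<- simulate_timecourse(config$sim)
    sim_pk <<- simulate_peaks(config$sim)
    stamp(sim_tc$counts, "counts.tsv", "simulate")
    stamp(sim_tc$truth, "truth_genes.tsv", "simulate")
    stamp(sim_pk$peaks, "peaks.tsv", "simulate")
    list(value = NULL, log = list(
      n_genes = nrow(sim_tc$truth), n_peaks = nrow(sim_pk$peaks)
    ))
  })

  clusters <- NULL
  run_stage("kinetics", function() {
    tc <- normalize_counts(sim_tc$counts)
    de <- call_differential_genes(tc, 0, config$de_timepoint,
                                  alpha = config$alpha,
                                  min_abs_log2fc = config$min_abs_log2fc)
    cl <- cluster_kinetics(tc, de, k = config$k, seed = config$sim$seed)
    clusters <<- cl
    stamp(de, "de_genes.tsv", "kinetics")
    stamp(cl$clusters, "clusters.tsv", "kinetics")
    stamp(cl$trajectories, "trajectories.tsv", "kinetics")
    stamp(cl$members, "cluster_members.tsv", "kinetics")
    report$kinetics <<- list(
      n_differential = sum(de$direction != "ns"),
      t_half = setNames(
        as.list(round(cl$clusters$t_half, 4)), cl$clusters$label
      )
    )
    list(value = cl, log = list(
      n_in = nrow(sim_tc$truth), n_differential = sum(de$direction != "ns"),
      n_clusters_retained = sum(cl$clusters$retained)
    ))
  })

  acc <- NULL
  run_stage("accessibility", function() {
    atac <- filter(sim_pk$counts, .data$assay == "atac")
    cls <- classify_accessibility(atac, 0, config$peak_timepoint,
                                  alpha = config$alpha)
    acc <<- cls
    peaks <- left_join(sim_pk$peaks, select(cls, "peak_id", "class",
                                            "p_adjusted"),
                       by = "peak_id")
    dtest <- compare_motif_density(
      peaks$motif_density[peaks$class == "decreased"],
      peaks$motif_density[peaks$class == "unchanged"]
    )
    centering <- summit_centering(
      sim_pk$tf_peaks,
      select(peaks, "peak_id", "start", "end", "class")
    )
    stamp(cls, "accessibility_classes.tsv", "accessibility")
    stamp(dtest, "motif_density_test.tsv", "accessibility")
    stamp(centering, "summit_centering.tsv", "accessibility")
    report$accessibility <<- list(
      class_counts = as.list(table(cls$class)),
      motif_density_p = dtest$p_value,
      median_offset = setNames(
        as.list(centering$median_offset), centering$class
      )
    )
    list(value = cls, log = list(
      n_peaks = nrow(cls), n_decreased = sum(cls$class == "decreased")
    ))
  })

  run_stage("regulatory", function() {
    peaks <- sim_pk$peaks
    if (!is.null(acc)) {
      peaks <- left_join(peaks, select(acc, "peak_id", "class"),
                         by = "peak_id")
    }
    elements <- classify_elements(peaks, sim_pk$h3k27ac_peaks,
                                  sim_pk$genes,
                                  promoter_window = config$promoter_window)
    enh <- elements %>%
      filter(.data$kind == "active_enhancer") %>%
      left_join(
        sim_pk$counts %>%
          filter(.data$assay == "h3k27ac", .data$timepoint == 0) %>%
          group_by(.data$peak_id) %>%
          summarise(signal = sum(.data$count), .groups = "drop"),
        by = "peak_id"
      ) %>%
      mutate(signal = dplyr::coalesce(.data$signal, 0))
    ses <- call_super_enhancers(enh)
    dens <- enhancer_density_by_gene_class(sim_pk$genes, elements,
                                           window = config$density_window)
    assoc <- se_association(sim_pk$genes, ses, window = config$se_window,
                            seed = config$sim$seed)
    h3k_counts <- filter(sim_pk$counts, .data$assay == "h3k27ac")
    chg <- change_fraction_by_class(
      sim_pk$genes, elements, h3k_counts, 0, config$peak_timepoint,
      alpha = config$alpha, min_fc = config$min_fc,
      window = config$density_window, seed = config$sim$seed
    )
    links <- link_enhancers(sim_pk$activity, sim_pk$gene_activity,
                            sim_pk$contacts, elements, sim_pk$genes,
                            r_min = config$r_min)
    stamp(select(elements, -dplyr::any_of("se_locus")), "elements.tsv",
          "regulatory")
    stamp(ses$regions, "super_enhancers.tsv", "regulatory")
    stamp(dens$tests, "enhancer_density_tests.tsv", "regulatory")
    stamp(assoc, "se_association.tsv", "regulatory")
    stamp(chg, "change_fractions.tsv", "regulatory")
    stamp(links$links, "enhancer_links.tsv", "regulatory")
    report$regulatory <<- list(
      n_super_enhancers = sum(ses$regions$is_super),
      se_fraction = setNames(as.list(round(assoc$fraction, 4)),
                             assoc$class),
      loss_fraction = setNames(as.list(round(chg$loss_fraction, 4)),
                               chg$class),
      mean_links = setNames(as.list(round(links$by_class$mean_links, 4)),
                            links$by_class$class)
    )
    list(value = NULL, log = list(
      n_elements = sum(!is.na(elements$kind)),
      n_super_enhancers = sum(ses$regions$is_super)
    ))
  })

  run_stage("bursting", function() {
    tg <- config$sim$telegraph_params_by_condition
    fs <- simulate_fish(tg$uninduced, tg$induced, config$sim$n_cells,
                        seed = config$sim$seed)
    cmp <- compare_conditions(fs$condition0, fs$condition1,
                              alpha = config$alpha)
    stamp(select(cmp, -dplyr::any_of("sizes")), "burst_comparison.tsv",
          "bursting")
    report$bursting <<- list(
      fraction0 = cmp$fraction0, fraction1 = cmp$fraction1,
      fisher_p = cmp$fisher_p, size_t_p = cmp$size_t_p,
      modulation = cmp$modulation
    )
    list(value = NULL, log = list(n_cells = config$sim$n_cells,
                                  modulation = cmp$modulation))
  })

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
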