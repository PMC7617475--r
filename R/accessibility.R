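# Differential chromatin accessibility: classification of peaks by early
# change, the binding-motif count/density statistic, signal metaprofiles
# around peak centres, and TF summit centering.

#' Classify peaks by early accessibility change
#'
#' Applies the same negative-binomial Wald machinery as
#' [call_differential_genes()] to per-peak counts at two timepoints and
#' classifies each peak: `decreased` (padj < `alpha`, negative fold change),
#' `increased` (padj < `alpha`, positive fold change), `unchanged`
#' (padj > `unchanged_alpha` and |log2FC| <= `unchanged_lfc`) and `other`
#' for peaks meeting neither rule. The four classes partition the peak set.
#'
#' @param peak_counts Long tibble `(peak_id, timepoint, replicate, count)`;
#'   an `assay` column, if present, must already be filtered to one assay.
#'   Median-of-ratios normalization is applied unless a `norm_count` column
#'   (e.g. from [normalize_counts()] or external size factors) is present.
#' @param t_ref,t Reference and test timepoints (hours).
#' @param alpha Adjusted-p threshold for a significant change (default 0.01).
#' @param unchanged_alpha,unchanged_lfc Rule defining confidently unchanged
#'   peaks (defaults padj > 0.05, |log2FC| <= 0.2).
#' @return Tibble of class `accessibility_class` with columns `peak_id`,
#'   `base_mean`, `log2_fold_change`, `p_value`, `p_adjusted`, `class`.
#' @export
#' @examples
#' sim <- simulate_peaks(sim_config(seed = 1, n_reg_genes = 60,
#'                                  genome_length = 4e6, n_peaks = 250))
#' atac <- dplyr::filter(sim$counts, assay == "atac")
#' cls <- classify_accessibility(atac, t_ref = 0, t = 2)
#' table(cls$class)
classify_accessibility <- function(peak_counts, t_ref, t, alpha = 0.01,
                                   unchanged_alpha = 0.05,
                                   unchanged_lfc = 0.2) {
  if ("assay" %in% names(peak_counts) &&
      length(unique(peak_counts$assay)) > 1) {
    abort("`peak_counts` mixes assays; filter to one assay first")
  }
  norm <- if ("norm_count" %in% names(peak_counts)) {
    peak_counts
  } else {
    normalize_counts(peak_counts, id_col = "peak_id")
  }
  res <- nb_wald_test(norm, "peak_id", t_ref, t)
  res <- res %>%
    mutate(class = case_when(
      .data$p_adjusted < alpha & .data$log2_fold_change < 0 ~ "decreased",
      .data$p_adjusted < alpha & .data$log2_fold_change > 0 ~ "increased",
      .data$p_adjusted > unchanged_alpha &
        abs(.data$log2_fold_change) <= unchanged_lfc ~ "unchanged",
      TRUE ~ "other"
    )) %>%
    select(-"dispersion", -"stat")
  class(res) <- c("accessibility_class", class(res))
  res
}

#' Count binding-motif occurrences in a DNA sequence
#'
#' Scans every start position on the given strand and counts possibly
#' overlapping occurrences of each motif; `N` never matches. The default
#' motif set (GGAA, TTCC, GGGA, TCCC) is closed under reverse complement,
#' so total counts are strand-symmetric.
#'
#' @param sequence DNA string over `A`, `C`, `G`, `T`, `N` (case
#'   insensitive).
#' @param motifs Character vector of motifs.
#' @return A list with `counts` (named integer vector, one per motif) and
#'   `total` (their sum).
#' @export
#' @examples
#' count_motifs("GGAAGGAA")$counts
#' count_motifs("GGGAA")$total  # overlapping GGGA + GGAA
count_motifs <- function(sequence,
                         motifs = c("GGAA", "TTCC", "GGGA", "TCCC")) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) {
    abort("`sequence` must be non-empty")
  }
  seq_up <- toupper(sequence)
  if (grepl("[^ACGTN]", seq_up)) {
    abort("`sequence` must contain only A, C, G, T, N")
  }
  L <- nchar(seq_up)
  counts <- vapply(motifs, function(m) {
    w <- nchar(m)
    if (w > L) {
      return(0L)
    }
    starts <- seq_len(L - w + 1)
    sum(substring(seq_up, starts, starts + w - 1) == m)
  }, integer(1))
  list(counts = counts, total = sum(counts))
}

#' Motif density per base pair
#'
#' The motif statistic of a peak: total motif count divided by the peak
#' length in bp.
#'
#' @param total Total motif count(s).
#' @param width Peak length(s) in bp, positive.
#' @return Density in motifs per bp (vectorized).
#' @export
#' @examples
#' motif_density(5, 250)
motif_density <- function(total, width) {
  check_non_negative(total, "total")
  check_positive(width, "width")
  total / width
}

#' Compare motif densities between two peak classes
#'
#' Two-sided Wilcoxon rank-sum test (mid-ranks for ties) on per-peak motif
#' densities, e.g. decreased-accessibility versus unchanged peaks.
#'
#' @param density_a,density_b Numeric vectors of per-peak densities, both
#'   non-empty.
#' @return One-row tibble `(statistic, p_value, n_a, n_b, median_a,
#'   median_b)`.
#' @export
compare_motif_density <- function(density_a, density_b) {
  if (length(density_a) == 0 || length(density_b) == 0) {
    abort("both groups must be non-empty")
  }
  wt <- suppressWarnings(
    wilcox.test(density_a, density_b, alternative = "two.sided")
  )
  tibble(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_a = length(density_a), n_b = length(density_b),
    median_a = median(density_a), median_b = median(density_b)
  )
}

#' Mean signal metaprofile around a set of centres
#'
#' Averages a binned genome-wide signal track over windows of
#' `[-flank, +flank]` bp centred on the given positions, in `n_bins`
#' equal-width output bins. Peaks are unstranded, so no strand flipping is
#' performed. Windows extending beyond the track are dropped (default) or
#' clipped to the track boundary.
#'
#' @param track Numeric vector of binned coverage; element `i` covers
#'   genomic positions `[(i-1) * bin_width, i * bin_width)`.
#' @param centers Genomic positions (bp) to centre windows on; non-empty.
#' @param flank Half-window size in bp (default 1000).
#' @param n_bins Number of output bins (default 100).
#' @param bin_width Track resolution in bp per element (default 10).
#' @param out_of_bounds `"drop"` (default) or `"clip"`.
#' @return Tibble of class `metaprofile` with `bin_center` (bp offset from
#'   the centre) and `mean_signal`; the number of contributing windows is in
#'   attribute `n_intervals`.
#' @export
#' @examples
#' track <- rep(1, 1000)
#' mp <- metaprofile(track, centers = c(3000, 5000), flank = 500,
#'                   n_bins = 20, bin_width = 10)
#' all(mp$mean_signal == 1)
metaprofile <- function(track, centers, flank = 1000, n_bins = 100,
                        bin_width = 10,
                        out_of_bounds = c("drop", "clip")) {
  out_of_bounds <- match.arg(out_of_bounds)
  if (length(centers) == 0) {
    abort("`centers` must be non-empty")
  }
  stopifnot(is.numeric(track), length(track) > 0, flank > 0, n_bins > 0)
  track_len <- length(track) * bin_width
  offsets <- -flank + (seq_len(n_bins) - 0.5) * (2 * flank / n_bins)
  if (out_of_bounds == "drop") {
    ok <- centers - flank >= 0 & centers + flank <= track_len
    centers <- centers[ok]
    if (length(centers) == 0) {
      abort("all windows fall outside the track; consider out_of_bounds = 'clip'")
    }
  }
  pos <- outer(centers, offsets, `+`)
  pos <- pmin(pmax(pos, 0), track_len - 1e-9)
  idx <- pmin(pmax(floor(pos / bin_width) + 1, 1), length(track))
  vals <- matrix(track[idx], nrow = length(centers))
  out <- tibble(bin_center = offsets, mean_signal = colMeans(vals))
  attr(out, "n_intervals") <- length(centers)
  class(out) <- c("metaprofile", class(out))
  out
}

#' Summit-to-peak-centre offsets by accessibility class
#'
#' For each TF-binding summit falling inside an accessibility peak, records
#' the absolute offset between the summit and the peak midpoint
#' (`floor((start + end) / 2)`), and summarises the offset distribution per
#' accessibility class. A TF whose binding drives the accessibility change
#' shows near-zero median offsets in the decreased class only.
#'
#' @param tf_peaks Tibble with a `summit` column (bp positions).
#' @param atac_peaks Tibble `(peak_id, start, end, class)` of
#'   non-overlapping accessibility peaks with class labels.
#' @return Tibble `(class, n, median_offset)`; zero rows (with attribute
#'   `no_overlap = TRUE`) when no summit falls inside any peak.
#' @export
summit_centering <- function(tf_peaks, atac_peaks) {
  stopifnot("summit" %in% names(tf_peaks),
            all(c("start", "end", "class") %in% names(atac_peaks)))
  ap <- arrange(atac_peaks, .data$start)
  if (any(ap$start[-1] < ap$end[-nrow(ap)])) {
    abort("`atac_peaks` must be non-overlapping")
  }
  idx <- interval_index_of(tf_peaks$summit, ap$start, ap$end)
  hit <- !is.na(idx)
  if (!any(hit)) {
    out <- tibble(class = character(0), n = integer(0),
                  median_offset = numeric(0))
    attr(out, "no_overlap") <- TRUE
    return(out)
  }
  mid <- interval_midpoint(ap$start[idx[hit]], ap$end[idx[hit]])
  tibble(
    class = ap$class[idx[hit]],
    offset = abs(tf_peaks$summit[hit] - mid)
  ) %>%
    group_by(.data$class) %>%
    summarise(n = n(), median_offset = median(.data$offset),
              .groups = "drop")
}
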