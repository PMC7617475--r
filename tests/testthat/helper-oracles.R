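# Independent oracles and small fixture builders used across the suite.
# These deliberately take different computational routes from the package
# functions they check.

# Overlapping-occurrence motif count via perl lookahead regex.
regex_motif_count <- function(sequence, motif) {
  m <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Direct Benjamini-Hochberg step-up (independent of stats::p.adjust).
bh_direct <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Median-of-ratios size factors recomputed directly from a count matrix
# (features x samples), excluding features with any zero.
size_factors_direct <- function(m) {
  keep <- apply(m, 1, function(x) all(x > 0))
  geo <- exp(rowMeans(log(m[keep, , drop = FALSE])))
  apply(m[keep, , drop = FALSE], 2, function(col) median(col / geo))
}

# Fisher two-sided p by full enumeration with exact factorials (valid for
# totals well below 170), probability-ordering convention.
fisher_enum <- function(m) {
  m <- matrix(as.numeric(m), 2, 2)
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (n == 0) return(1)
  tab_prob <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    (factorial(r1) * factorial(r2) * factorial(c1) * factorial(n - c1)) /
      (factorial(n) * factorial(a) * factorial(b) * factorial(c) *
         factorial(d))
  }
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, tab_prob, numeric(1))
  obs <- probs[ks == m[1, 1]]
  min(sum(probs[probs <= obs * (1 + 1e-12)]), 1)
}

# Allele-level FISH table with a given number of bursting alleles.
make_fish_table <- function(n_cells, n_bursts, intensity = 10, radius = 2) {
  n_alleles <- 2L * n_cells
  stopifnot(n_bursts <= n_alleles)
  burst <- c(rep(TRUE, n_bursts), rep(FALSE, n_alleles - n_bursts))
  tibble::tibble(
    cell_id = rep(seq_len(n_cells), each = 2L),
    allele = rep(1:2, n_cells),
    burst = burst,
    Intensity_MaxIntensity = ifelse(burst, intensity, NA_real_),
    AreaShape_MeanRadius = ifelse(burst, radius, NA_real_)
  )
}

# Long count tibble from a gene x sample mean matrix with deterministic or
# NB noise; timepoints/replicates inferred from dimnames-free layout.
make_tc <- function(mu_mat, timepoints, n_reps = 2, dispersion = 0,
                    seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(nrow(mu_mat)))
  out <- expand.grid(
    replicate = seq_len(n_reps), timepoint = timepoints,
    gene = genes, stringsAsFactors = FALSE
  )
  mu <- mu_mat[cbind(
    match(out$gene, genes), match(out$timepoint, timepoints)
  )]
  out$count <- if (dispersion == 0) {
    round(mu)
  } else {
    rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  tibble::as_tibble(out[, c("gene", "timepoint", "replicate", "count")])
}
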