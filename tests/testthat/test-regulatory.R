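# Element classification, super-enhancer calling, enhancer association
# statistics and enhancer-gene linking.

test_that("element classification gates on H3K27ac then distance", {
  genes <- tibble::tibble(gene = "g1", class = "non_de", tss = 10000L)
  h3k <- tibble::tibble(start = c(9500L, 59500L), end = c(10500L, 60500L))
  atac <- tibble::tibble(
    peak_id = c("at_tss", "distal_marked", "unmarked"),
    start = c(9800L, 59800L, 120000L),
    end = c(10200L, 60200L, 120400L)
  )
  el <- classify_elements(atac, h3k, genes, promoter_window = 1000)
  expect_equal(el$kind[el$peak_id == "at_tss"], "active_promoter")
  expect_equal(el$kind[el$peak_id == "distal_marked"], "active_enhancer")
  expect_true(is.na(el$kind[el$peak_id == "unmarked"]))
  expect_error(classify_elements(atac, h3k, tibble::tibble(gene = "g")),
               "tss")
})

test_that("stitching merges nearby enhancers and is idempotent", {
  enh <- tibble::tibble(
    start = c(1000L, 7000L, 100000L, 130000L),
    end = c(2000L, 8000L, 101000L, 131000L),
    signal = c(10, 10, 10, 200)
  )
  se <- call_super_enhancers(enh, stitch_distance = 12500)
  # enhancers 5 kb apart are stitched into one region
  expect_equal(nrow(se$regions), 3)
  expect_true(any(se$regions$start == 1000 & se$regions$end == 8000))
  # stitching the stitched set changes nothing
  again <- call_super_enhancers(
    dplyr::rename(se$regions, signal = "total_signal"),
    stitch_distance = 12500
  )
  expect_equal(again$regions[, c("start", "end", "total_signal")],
               se$regions[, c("start", "end", "total_signal")])
  expect_error(call_super_enhancers(enh[1:2, ]), "at least 3")
})

test_that("the rank elbow recovers planted high-signal regions exactly", {
  set.seed(51)
  enh <- tibble::tibble(
    start = seq(0L, by = 50000L, length.out = 100),
    end = seq(0L, by = 50000L, length.out = 100) + 1000L,
    signal = c(runif(95, 80, 120), runif(5, 900, 1100))
  )
  se <- call_super_enhancers(enh)
  expect_equal(sum(se$regions$is_super), 5)
  # brute-force: the called set must be exactly the top 5 by signal
  top5 <- sort(se$regions$total_signal, decreasing = TRUE)[1:5]
  expect_setequal(se$regions$total_signal[se$regions$is_super], top5)
  # all-equal signals -> elbow undefined, no super-enhancers
  flat <- call_super_enhancers(
    tibble::tibble(start = enh$start, end = enh$end, signal = 5)
  )
  expect_equal(sum(flat$regions$is_super), 0)
  expect_true(is.na(flat$cutoff_signal))
})

test_that("enhancer counting uses closed windows around the TSS", {
  genes <- tibble::tibble(
    gene = c("far", "boundary"), class = c("non_de", "fast_repressed"),
    tss = c(1000000L, 50000L)
  )
  # enhancer midpoint exactly at TSS + window -> included
  elements <- tibble::tibble(
    peak_id = "e1", start = 69900L, end = 70100L, kind = "active_enhancer"
  )
  res <- enhancer_density_by_gene_class(genes, elements, window = 20000)
  expect_equal(res$counts$n_enhancers[res$counts$gene == "boundary"], 1L)
  expect_equal(res$counts$n_enhancers[res$counts$gene == "far"], 0L)
  # one bp further -> excluded
  res2 <- enhancer_density_by_gene_class(
    genes, dplyr::mutate(elements, start = start + 2L, end = end + 2L),
    window = 20000
  )
  expect_equal(res2$counts$n_enhancers[res2$counts$gene == "boundary"], 0L)
})

test_that("enhancer density separates the fast-repressed class by design", {
  cfg <- sim_config(seed = 52, n_reg_genes = 400, genome_length = 2.5e7,
                    n_peaks = 2500)
  pk <- simulate_peaks(cfg)
  el <- classify_elements(pk$peaks, pk$h3k27ac_peaks, pk$genes)
  res <- enhancer_density_by_gene_class(pk$genes, el)
  expect_true(all(res$tests$p_adjusted < 0.01))
  means <- tapply(res$counts$n_enhancers, res$counts$class, mean)
  expect_true(all(means[["fast_repressed"]] >
                    means[names(means) != "fast_repressed"]))
})

test_that("SE association fractions behave at the extremes", {
  genes <- tibble::tibble(
    gene = sprintf("g%d", 1:20),
    class = rep(c("fast_repressed", "non_de"), each = 10),
    tss = seq(100000L, by = 200000L, length.out = 20)
  )
  none <- se_association(
    genes,
    tibble::tibble(start = 1L, end = 2L, is_super = FALSE),
    seed = 1
  )
  expect_true(all(none$fraction == 0))
  blanket <- se_association(
    genes,
    tibble::tibble(start = 0L, end = 5000000L, is_super = TRUE),
    seed = 1
  )
  expect_true(all(blanket$fraction == 1))
  expect_true("random" %in% blanket$class)
})

test_that("links require correlation and contact jointly, monotonically", {
  ctx <- sprintf("ctx_%02d", 1:6)
  act <- c(1.1, 2.0, 0.4, 3.2, 1.8, 0.9)
  activity <- tibble::as_tibble(
    rbind(act, act, rep(1, 6)), .name_repair = ~ctx
  )
  activity$element_id <- c("perfect", "farcopy", "flat")
  activity <- activity[, c("element_id", ctx)]
  gene_activity <- tibble::as_tibble(rbind(act), .name_repair = ~ctx)
  gene_activity$gene <- "g1"
  gene_activity <- gene_activity[, c("gene", ctx)]
  elements <- tibble::tibble(
    peak_id = c("perfect", "farcopy", "flat"),
    start = c(10000L, 900000L, 30000L),
    end = c(10400L, 900400L, 30400L)
  )
  genes <- tibble::tibble(gene = "g1", class = "fast_repressed",
                          tss = 20000L)
  contacts <- tibble::tibble(
    element_id = c("perfect", "flat"), gene = "g1", contact = c(5, 5)
  )
  lk <- link_enhancers(activity, gene_activity, contacts, elements, genes,
                       r_min = 0.5, c_min = 1)
  links <- lk$links
  # identical activity and passing contact -> linked with correlation 1
  expect_equal(links$correlation[links$element_id == "perfect"], 1)
  expect_true(links$linked[links$element_id == "perfect"])
  # beyond the candidate radius -> not a candidate at all
  expect_false("farcopy" %in% links$element_id)
  # zero-variance activity -> skipped and flagged
  expect_true(links$flagged[links$element_id == "flat"])
  expect_false(links$linked[links$element_id == "flat"])
  # correlation equals the direct covariance / (sd * sd) formula
  a <- c(0.2, 1.4, 0.9, 2.5, 0.1, 1.8)
  activity2 <- activity
  activity2[activity2$element_id == "perfect", ctx] <- as.list(a)
  lk2 <- link_enhancers(activity2, gene_activity, contacts, elements,
                        genes, r_min = 0.5, c_min = 1)
  direct <- sum((a - mean(a)) * (act - mean(act))) /
    (sqrt(sum((a - mean(a))^2)) * sqrt(sum((act - mean(act))^2)))
  expect_equal(lk2$links$correlation[lk2$links$element_id == "perfect"],
               direct, tolerance = 1e-12)
  # raising thresholds never adds links
  stricter <- link_enhancers(activity, gene_activity, contacts, elements,
                             genes, r_min = 0.9, c_min = 10)
  expect_true(all(which(stricter$links$linked) %in% which(links$linked)))
  expect_error(
    link_enhancers(activity[, 1:4], gene_activity[, 1:4], contacts,
                   elements, genes),
    "5"
  )
})

test_that("change fractions are calibrated at the null and saturate", {
  genes <- tibble::tibble(
    gene = sprintf("g%d", 1:10),
    class = rep(c("fast_repressed", "non_de"), each = 5),
    tss = seq(50000L, by = 100000L, length.out = 10)
  )
  elements <- tibble::tibble(
    peak_id = sprintf("e%03d", 1:300),
    start = rep(genes$tss, 30) - 5000L,
    end = rep(genes$tss, 30) - 4600L,
    kind = "active_enhancer"
  )
  elements$start <- elements$start + rep(seq(0L, 14500L, by = 500L),
                                         each = 10)
  elements$end <- elements$start + 400L
  # null: stationary counts -> both fractions below the false-positive bar
  set.seed(61)
  null_counts <- tibble::tibble(
    peak_id = rep(elements$peak_id, each = 4),
    timepoint = rep(c(0, 0, 2, 2), 300),
    replicate = rep(c(1, 2, 1, 2), 300),
    count = rnbinom(1200, mu = 300, size = 20)
  )
  chg0 <- change_fraction_by_class(genes, elements, null_counts, 0, 2,
                                   seed = 1)
  expect_true(all(chg0$loss_fraction < 0.02))
  expect_true(all(chg0$gain_fraction < 0.02))
  # saturated effect: everything halved with tiny dispersion -> loss ~ 1
  # (unit size factors supplied: a global shift is the signal here, not a
  # composition artefact for median-of-ratios to remove)
  half_counts <- null_counts
  mu <- ifelse(half_counts$timepoint == 0, 400, 200)
  set.seed(62)
  half_counts$count <- rnbinom(1200, mu = mu, size = 1000)
  half_counts$size_factor <- 1
  half_counts$norm_count <- half_counts$count
  chg1 <- change_fraction_by_class(genes, elements, half_counts, 0, 2,
                                   seed = 1)
  expect_true(all(chg1$loss_fraction > 0.95))
})
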