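# tfresponse

Time-resolved analysis of transcription-factor induction experiments, for
researchers studying how an inducible TF (for example a repressor such as
IKZF1 entering the nucleus on tamoxifen induction) reshapes transcription
and chromatin. The package covers the four analysis layers such studies
combine:

1. **Kinetics** — nascent-transcription count time courses are normalized
   (median-of-ratios), tested for differential expression between
   timepoints (negative-binomial Wald test, method-of-moments dispersion,
   Benjamini–Hochberg; called at padj < 0.01, |log2FC| > 1), clustered by
   K-means on min–max scaled trajectories, filtered for monotonicity
   (|Spearman ρ| ≥ 0.8), and summarised by the half-maximal response time
   *t*½ — the first crossing of $(\max+\min)/2$ on the cluster mean
   trajectory, linearly interpolated.
2. **Accessibility** — peaks are classified as `decreased`, `increased`,
   `unchanged` (padj > 0.05, log2FC ∈ [−0.2, 0.2]) or `other` with the
   same NB machinery; a TF-binding motif statistic counts possibly
   overlapping occurrences of GGAA/TTCC/GGGA/TCCC per peak, with density =
   count / peak length (bp), compared between classes by Wilcoxon rank-sum;
   metaprofiles and TF-summit centering summarise signal around peaks.
3. **Regulatory elements** — H3K27ac-overlapping accessible sites become
   active promoters (±1 kb of a TSS) or enhancers; super-enhancers are
   called ROSE-style (12.5 kb stitching, rank-signal elbow at the slope-1
   tangent); per-gene-class statistics quantify enhancer density (±20 kb),
   SE association (±50 kb), H3K27ac loss/gain fractions (padj < 0.01,
   FC > 1.5) against seeded random-gene controls, and enhancer–gene links
   (activity correlation ≥ 0.5 plus contact frequency above background).
4. **Bursting** — allele-level FISH tables give the burst fraction
   (bursts / 2·cells) and burst size (max intensity + mean radius);
   conditions are compared by an exact Fisher test (implemented in
   log-space, enumeration-verified) and Student's t-test, yielding a
   frequency/size/both/none modulation verdict under the two-state
   telegraph model (stationary ON probability `k_on/(k_on+k_off)`).

A seeded synthetic-data generator (`sim_config()`, `simulate_timecourse()`,
`simulate_peaks()`, `simulate_fish()`) reproduces the statistical structure
of all inputs with known ground truth, so every stage is validated by
parameter recovery — no external downloads required.

## Worked example

```r
library(tfresponse)
library(dplyr)

sim <- simulate_timecourse(sim_config(seed = 42, n_genes = 2000))
tc  <- normalize_counts(sim$counts)
de  <- call_differential_genes(tc, t_ref = 0, t = 24)
count(de, direction)
#>   direction     n
#> 1 down        385
#> 2 ns         1213
#> 3 up          402

cl <- cluster_kinetics(tc, de, k = 4, seed = 42)
tidy(cl)
#>   cluster n_genes direction    rho t_half retained label
#> 1       1     207 down      -1      0.842 TRUE     fast_repressed
#> 2       2     178 down      -0.964  7.41  TRUE     slow_repressed
#> 3       3     190 up         1      9.30  TRUE     slow_activated
#> 4       4     212 up         1      3.23  TRUE     activated
```

The generator planted 200 genes per responsive class (the other 1200 are
non-responding background); the stage recovers the four kinetic classes
and their ordering, with the fast-repressed cluster reaching half-maximal
repression at ~0.84 h. The slow classes' half-times are compressed on this
24 h grid because their trajectories have not plateaued — sample longer to
estimate slow kinetics (see the methods vignette).

```r
fs <- simulate_fish(telegraph_params(1, 4), telegraph_params(0.5, 4),
                    n_cells = 700, seed = 42)
cmp <- compare_conditions(fs$condition0, fs$condition1)
glance(cmp)
#>   fisher_p size_t_p modulation
#> 1 5.88e-16    0.720 frequency
```

Halving `k_on` (induction) drops the burst fraction from 0.211 to 0.101
while burst sizes stay put: the comparison correctly reports frequency —
not size — modulation, the signature of a repressor lowering burst
probability.

`run_pipeline(pipeline_config(sim = sim_config(seed = 1)), "out/")` chains
simulate → kinetics → accessibility → enhancers → bursting and writes
stage-stamped TSV tables, a JSON report and a manifest; reruns with the
same configuration are byte-identical. Result objects have
`tidy()`/`glance()` and `autoplot()` methods.

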