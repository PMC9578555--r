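# hapsweep

Haplotype-based selective sweep scans with demographic calibration.

## The problem

Recently founded populations are the worst place to run an off-the-shelf
selection scan: founder bottlenecks and rapid post-glacial expansion leave
long haplotypes, reduced diversity and shifted allele frequencies — the same
footprints a selective sweep leaves. Marine invertebrates that recolonized
shelf habitat after the last glacial maximum (reef corals are the motivating
case) show exactly this history: three genetically distinct populations,
split within a few thousand generations, each through its own bottleneck,
with very low ongoing gene flow. hapsweep is for population geneticists who
want to scan such data for sweeps *and* defend the outlier thresholds
against the demographic null.

## What it implements

- **Haplotype homozygosity statistics from first principles**: EHH curves,
  iHS, nSL, XP-EHH and XP-nSL, with standardization in 50 allele-frequency
  bins. EHH at marker *x* is the fraction of carrier pairs identical from
  the core to *x*; iHH integrates it over distance, and
  iHS = ln(iHH_A/iHH_D).
- **Population branch statistic**: per-SNP branch lengths
  T = −ln(1 − F_ST) from Hudson's estimator (ratio-of-averages
  aggregation), PBS_A = (T_AB + T_AC − T_BC)/2.
- **A forward Wright–Fisher simulator** of a three-population
  founder-effect demography (two splits, founder bottlenecks with
  exponential growth, constant offshore–offshore migration, delayed
  inshore–offshore secondary contact, optional hard sweep from standing
  variation), plus a constant-Ne counterfactual. Neutral simulations
  calibrate PBS thresholds at a chosen false-positive rate.
- **The window outlier procedure**: flag extreme SNPs (|iHS| > 2, XP
  statistics above their 99th percentile per ordered pair), rank 50-kb
  windows by flagged-SNP proportion, keep the top 1%, union statistics per
  population, drop windows iHS-significant in more than one population, and
  intersect with PBS-significant SNPs.
- **Window diversity statistics** (π, Tajima's D, d_xy, 70%-callable
  filter), LD decay, inbreeding F, homozygosity-by-descent segments,
  near-privately fixed SNPs, folded joint site-frequency spectra.
- **GO enrichment** at gene and 50-kb-region level by Fisher's exact test.
- **Alignment-free d2s** k-mer dissimilarity between read sets with
  classical MDS ordination.

## A worked example

Simulate the founder-effect demography with a hard sweep in the inshore
population, scan, calibrate, and intersect:

```r
library(hapsweep)
pops <- c("IN", "NO", "SO")
m <- demography_imc_scaled(scale = 100, L = 2.5e5, n_scaffolds = 6)
sel <- selection_spec("IN", s = 1, h = 0.5, origin_time = 13,
                      focal_position = 1.25e5, mode = "standing",
                      freq_range = c(0.02, 0.2), min_freq = 0.9)
r <- wf_simulate(m, n_per_pop = 15, selection = sel, seed = 5201)
r$sweep_truth
#>   scaffold_id position freq_IN freq_NO   freq_SO
#> 1  scaffold_1   126150    0.98   0.125 0.3142857

grid <- make_windows(setNames(rep(2.5e5, 6), paste0("scaffold_", 1:6)), 5e4)
scan <- sweep_scan(r$panels, pops, grid)

neutral <- lapply(1:12, function(i)
  wf_simulate(demography_imc_scaled(scale = 100, L = 2.5e5),
              n_per_pop = 10, seed = 21000 + i)$panels[[1]])
th <- lapply(pops, function(p)
  calibrate_pbs_threshold(neutral, p, fpr = 0.01, pops = pops))
sapply(th, `[[`, "threshold")
#> [1] 0.7817978 0.5197225 0.4861613

pbs_df <- do.call(rbind, lapply(r$panels, function(p)
  cbind(scaffold_id = p$scaffold_id, pbs_per_snp(p, pops))))
pbs_overlap(scan$regions, pbs_df, th)
#>    scaffold_id  start    end pop       stats n_stats   max_prop pbs_overlap   pbs_max
#> 1   scaffold_1  50000 100000  IN       xpehh       1 0.11165049        TRUE 1.5348886
#> 2   scaffold_1 100000 150000  IN       xpnsl       1 0.15555556        TRUE 1.5896218
#> 3   scaffold_2 200000 250000  IN         ihs       1 0.15789474       FALSE 0.3355987
#> ...                                     (11 rows)
```

The planted sweep (truth: scaffold_1 position 126150, swept to 98% inshore
while staying at 12-31% offshore) is recovered as the window
[100000, 150000) for population IN — along with its flanking window, since
the swept haplotype spans both — containing SNPs whose inshore PBS (up to
1.59) far exceeds the neutral-calibrated inshore threshold (0.78).  Note
the threshold ordering IN > NO, SO: the severely bottlenecked inshore
branch needs a higher bar, which is the point of calibrating on the
demographic null rather than using one genome-wide cutoff.  Candidate
windows in other populations without PBS support (pbs_overlap FALSE) are
what the calibration step is there to discount.

The same stages run from a YAML config over a VCF + population map via
`run_pipeline("config.yaml")`, writing window statistics (TSV), sweep
regions (BED) and thresholds under an output directory.

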