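---
title: "Demography-calibrated selective sweep scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demography-calibrated selective sweep scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hapsweep detects selective sweeps in phased population genomic data and,
crucially, calibrates its outlier thresholds against an explicit demographic
null.  Founder bottlenecks mimic sweeps: both leave long haplotypes, reduced
diversity and shifted allele frequencies, so a scan that ignores demography
over-reports selection in recently founded populations.  The package couples
three components: haplotype-homozygosity statistics computed from first
principles, the population branch statistic (PBS) built from Hudson's Fst,
and a forward Wright-Fisher simulator of a three-population founder-effect
history used to set false-positive-controlled PBS thresholds and to provide
study-condition data for every test in the package.

This vignette records the models, the numerical choices, and the reasoning
behind design decisions that were genuinely open.

## The demographic model

`demography_imc()` parameterizes the history the scan is calibrated
against: an ancestral population of diploid size $N_{anc}$; a split at
$T_{div2}$ generations before present founding an inshore deme (IN) through
a bottleneck of size $N^f_{IN}$; a second split at $T_{div1}$ dividing the
offshore ancestor into north (NO) and south (SO) offshore demes, each
through its own founder bottleneck; exponential growth of every founded
deme from its founder size at the split to its present size; constant
offshore-offshore migration at per-individual probability $m_{off}$ since
$T_{div1}$; and inshore-offshore migration at $m_{sec}$ switched on only at
a secondary-contact time $T_{sec}$.  This is the isolation-with-migration
variant in which contact between inshore and offshore is delayed ("IMc"):
the configuration that best explains three coral populations in
northwestern Australia that diverged rapidly after the post-glacial
re-flooding of the shelf, with the strongest bottleneck inshore.

Generations are discrete.  Each generation applies, in order: reproduction
(random mating within a deme with selfing excluded, per-gamete crossover
count Poisson($rec \cdot L$) at uniform positions, new mutations
Poisson($\mu \cdot L$) at uniform continuous coordinates under
infinite-sites), then conservative migration (each individual is replaced
by a copy of a random individual from the partner deme with the active
probability), then, if configured, the beneficial-allele event.  Selection
is viability weighting of parents in the focal deme with genotype fitnesses
$1, 1+hs, 1+s$.

### Parameter scaling

The fitted parameter values behind the real analysis are not publicly
tabulated, so the package's defaults are *shaped* like that history rather
than equal to it.  They derive from a single large-population reference --
diploid ancestral size 30 000 (the value assumed for allele-age estimation
in the source system), $\mu = 1.2\times10^{-8}$ and
$rec = 3.2\times10^{-8}$ per base per generation, splits at 1440 and 960
generations (about 7 and 5 thousand years at 5 years per generation),
secondary contact at 480 generations, migration probability
$10^{-4}$ per individual per generation -- rescaled by a factor $k$
(`demography_imc_scaled(scale = k)`): sizes and times divided by $k$, the
per-generation rates $\mu$, $rec$, $m$ multiplied by $k$.  This preserves
the population-scaled compounds $4N\mu$, $4Nrec$, $T/N$ and $Nm$ that
control diversity, linkage, drift and differentiation, which is the
standard device for making forward simulation tractable.  The desk default
is $k = 30$ ($N_{anc} = 1000$, about 20 s per 500-kb scaffold); the test
suite and the acceptance script use $k = 100$ ($N_{anc} = 300$, about
1.5 s per 250-kb scaffold).  Founder and present sizes (3%, 6%, 5% of the
ancestral size for IN, NO, SO founders; present sizes ordered
NO > SO > IN) encode the qualitative findings that the inshore bottleneck
was the most severe and the north offshore deme retains the most
diversity.

Two artifacts of aggressive rescaling are worth knowing about.  First,
drift is fast everywhere, so the constant-size counterfactual (below) is
itself somewhat drifty at $k = 100$; directional comparisons remain clear
but per-pair margins shrink.  Second, haplotype-tract length scales
inversely with the rescaled recombination rate, so length thresholds
(homozygosity-by-descent segment minima, LD distances) must be read on the
rescaled map, not the real one.

### The constant-Ne counterfactual

`constant_n_variant()` returns the same model with all bottlenecks and
growth removed: the total population is held at $N_{anc}$ and divided
equally among the demes extant in each epoch (1, then 2, then 3), with
split times and migration untouched.  Comparing differentiation under the
two models isolates the contribution of founder effects: in the package's
simulations the full model's mean pairwise Fst exceeds the counterfactual's
in every replicate pair, with the inshore-offshore contrast reduced roughly
3-5 fold -- the qualitative signature that population-size change, not
ongoing gene flow restriction alone, drives the differentiation.

### What the simulator does and does not emulate

The generator produces phased, ancestrally polarized biallelic haplotypes
with truth available (sweep position and final frequencies), which is what
the scan consumes.  It does not model: variable recombination or mutation
rate along the genome, gene conversion, genotyping error or missingness,
unphased or unpolarized sites, selection outside the focal deme, or linked
background selection.  Passing tests therefore demonstrate correctness of
the statistics and the calibration logic under a clean, known null -- not
robustness to the full messiness of real data.

## Haplotype statistics

`ehh_curve()` implements extended haplotype homozygosity from its
definition: EHH at marker $x$ is the fraction of carrier pairs identical at
every SNP between the core and $x$, inclusive; it equals 1 at the core and
is non-increasing outward.  `within_pop_scan()` integrates EHH over
physical distance by the trapezoid rule separately for derived and
ancestral carriers (iHH$_D$, iHH$_A$), truncating at the first marker whose
EHH falls below `ehh_cutoff` (default 0.05, that trapezoid included).  A
core whose curve has not reached the cutoff when it hits the scaffold edge
or `max_extend` (default 1 Mb) is reported `skipped_truncated` rather than
integrated partially; this hard-truncation-with-skip replaces the gap
penalty used by some scan software and only matters in sparse or
edge-proximal regions.  Physical distance stands in for genetic distance
throughout, consistent with assuming a uniform recombination map.

Raw scores are $iHS = \ln(iHH_A/iHH_D)$,
$XP\!-\!EHH = \ln(iHH_{popA}/iHH_{popB})$.  For the cross-population
statistics iHH is integrated over *all* haplotypes of each population; the
walk then starts from the core homozygosity (the fraction of pairs agreeing
at the core itself), which makes the within- and cross-population
definitions a single formula, and the statistic is exactly antisymmetric
under swapping the populations.  nSL and XP-nSL use the same machinery with
distance measured in segregating sites and no EHH cutoff: the mean pairwise
identity length equals the core value plus the sum of per-step EHH values,
capped at `max_sites` (default 100 sites, matching common practice for this
statistic) per direction.

Scores are standardized in 50 equal-width derived-allele-frequency bins
(`normalize_bins()`); bins with fewer than 20 scores merge into their
nearest populated neighbour.  Equal-width bins were chosen over
equal-count ones; with `n_bins = 1` the operation degenerates to a global
z-score, which the tests exploit.  After normalization the |iHS| > 2 flag
rate on null scores is the two-sided normal tail, about 4.55%.

## The window outlier procedure

Extreme SNPs are flagged per statistic: $|iHS| > 2$; XP-EHH and XP-nSL
above their empirical 99th percentile, computed per ordered population pair
(the pooled alternative is one flag away).  Within 50-kb tiling windows the
proportion of flagged SNPs among scored SNPs is ranked, windows with fewer
than `min_snps = 10` scored SNPs are excluded, and windows at or above the
99th percentile of proportions are candidates (ties included, so slightly
more than 1% can qualify; windows with zero flagged SNPs never qualify).
Ranking is per population and per statistic; candidates are unioned per
population.  A window that is an iHS candidate in more than one population
loses its iHS support everywhere -- the scan targets sweeps unique to one
population, and this is the stated uniqueness rule; no analogous rule is
applied to the cross-population statistics, which already contrast
populations.

PBS is computed per SNP from the three pairwise Hudson Fst ratios,
$T = -\ln(1 - F_{st})$, focal branch
$PBS_A = (T_{AB} + T_{AC} - T_{BC})/2$.  Negative pairwise Fst is clamped
to zero before the log (inside `pbs()` only); $F_{st} \ge 1$ produces an
infinite branch, flagged, never silently dropped.  Thresholds come from
neutral simulation under the calibrated demography:
`calibrate_pbs_threshold()` takes the empirical 99th percentile (a type-1
quantile, i.e. an order statistic) of per-SNP focal-branch PBS pooled over
neutral replicates.  Because the inshore branch drifts hardest, its
threshold is the largest -- the package's tests require this ordering in at
least 9 of 10 independent calibration runs at the test scale.  Monte-Carlo error for the held-out
false-positive check is computed at the replicate level
(sd of per-scaffold exceedance / $\sqrt{K}$): SNPs within a simulated
scaffold share a genealogy, so a per-SNP binomial standard error would
understate the true Monte-Carlo error several-fold.

A final `pbs_overlap()` step marks each candidate window by whether it
contains at least one SNP whose focal-branch PBS exceeds that population's
threshold.  In the planted-sweep validation (hard sweep from standing
variation at 2-20% initial frequency, conditioned to reach 90% by
sampling), the sweep window is recovered with PBS support in the focal
population in at least 80% of replicates at the package's test scale, and
in no other population in the clear majority; occasional cross-population hits
are genuine adaptive introgression of the swept haplotype through
secondary-contact migration followed by drift, not false positives of the
machinery.

## Diversity statistics and their conventions

Coordinates: VCF positions are 1-based; all windows and BED intervals are
0-based half-open, converted in one place.  Windows tile from coordinate 0
(whether to tile from the first SNP instead was an open choice; 0 keeps
grids comparable across panels).  The "10-kb windows with 2-kb overlap"
idiom is implemented as sliding windows of 10 kb with step 2 kb; the step
is configurable.

Per window and population: $\pi$ per callable base uses the unbiased
per-site heterozygosity $2p(1-p)\,n/(n-1)$; Tajima's D uses the standard
$a_1 \ldots e_2$ constants from the haplotype count and $S$; $d_{xy}$ per
callable base uses $p_1(1-p_2) + p_2(1-p_1)$.  Windows under 70% callable
are flagged excluded.  The window table reports D as missing below
$S = 4$; the `tajima_d()` primitive itself computes it for any $S \ge 1$
(the variance term, not the site count, is the mathematical constraint).
Hudson Fst aggregates as a ratio of averages (sum of per-site numerators
over sum of denominators), negative site numerators retained; whether to
average ratios instead was open, and ratio-of-averages is the estimator
with the better bias properties.  The Weir-Cockerham variant is deliberately
not implemented: PBS is built from the Hudson values, and one definition
throughout keeps window and branch statistics consistent.

Homozygosity-by-descent segments use an explicit per-site LOD
(homozygote probability $p(1-e) + ep^2$ under HBD versus Hardy-Weinberg,
heterozygote $e \cdot 2p(1-p)$, error rate $e = 0.005$) and extract
maximal-scoring disjoint segments by recursive best-segment search,
reporting those with LOD $\ge 3$ and length above a floor that should be
scaled with the recombination map (50 kb at real scale).  This is a
deliberate simplification of full HBD likelihood models; the package's
claims about it are directional (bottlenecked populations carry more HBD),
not value-matching.

## Enrichment

GO enrichment is Fisher's exact test (one-sided hypergeometric upper tail)
at two unit levels: genes (target = genes overlapping sweep regions,
background = all annotated genes) and 50-kb regions, where a region
inherits every GO term of genes it overlaps by at least 1 bp and sweep
regions are contrasted against all grid regions.  The region-level test is
the headline: genes cluster physically, so region units are closer to
independent.  Terms are reported significant at raw $p < 0.005$ with at
least two distinct supporting sweep regions; no multiple-testing correction
is applied at the decision point (a Benjamini-Hochberg column is emitted
for information).  Ancestor propagation through the GO graph is off by
default and terms are used as annotated.  The weight01-style decorrelation
of some ontology tools is out of scope; classic Fisher is used at both
levels.

## k-mer dissimilarity and ordination

`count_kmers()` counts canonical k-mers (lexicographic minimum of word and
reverse complement; odd $k$ keeps this unambiguous) and fits an order-0
nucleotide background per read set.  The d2s dissimilarity centers counts
against expectation, $\tilde X_w = X_w - n \, p_w$, and normalizes a
D2-type inner product into $[0, 1]$ with 0 at identity.  The default
$k = 21$ is the community default for k-mer profiling; the upstream
analysis this emulates does not state its $k$, so it is a flagged,
configurable choice, as is the order-0 background.  `classical_mds()` is
Torgerson scaling (delegated to `stats::cmdscale`) with a sign convention
(largest-magnitude loading positive) so embeddings are reproducible; inputs
with more than half their eigenvalue mass negative trigger a warning.

## Numerical and reproducibility choices

The engine's RNG is a Mersenne-Twister 64 stream with hand-rolled uniform
and Poisson draws, so results depend only on the seed and not on compiler
library internals.  One seeded generator drives each scaffold; scaffold and
retry offsets are derived arithmetically from the user seed.  A selection
specification with $s = 0$ takes exactly the neutral code path and
reproduces the neutral output bit-for-bit at the same seed.  Fixed
mutations are purged from the population every 100 generations (the
beneficial allele is exempt).  Continuous mutation coordinates are floored
to 1-based integer bp on output; in the rare collision the first site is
kept.  Establishment-conditioned sweeps retry with derived sub-seeds up to
`max_tries` and error afterwards, reporting the count.

## Problem sizes used by the tests

Oracle tests run on panels of at most 20 haplotypes and 30 SNPs against
explicit pair-enumeration implementations (tolerance $10^{-10}$ or
tighter).  Simulation-based checks use the $k = 100$ rescaling: 80 neutral
250-kb scaffolds for threshold calibration and held-out validation, 20
planted-sweep replicates of 6 scaffolds at 15 samples per population, 10
full/constant-Ne replicate pairs, and 60 constant-size replicates for the
site-frequency-spectrum and diversity expectations.  The SFS chi-square
test thins to every 5th SNP first: SNPs within a replicate share
genealogy, and the thinned test has approximately the nominal null
distribution while the unthinned one does not.  These sizes are the
package's chosen study conditions; the same machinery runs unchanged at
larger scales.

## Known limitations

Thresholds calibrated under a mis-specified demography inherit its biases;
the calibration is only as good as the fitted null model.  The EHH skip
semantics lose edge-proximal cores on short scaffolds.  The simulator's
discrete generations and conservative migration are one of several
defensible conventions; absolute values of migration-sensitive quantities
at heavy rescaling should be interpreted qualitatively.  The enrichment
module treats GO terms as flat labels unless an ontology graph is supplied
for ancestor propagation.  The d2s module's background is order-0; repeat-
or composition-driven structure beyond single-nucleotide frequencies is
absorbed into the signal, not the background.
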