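---
title: "Methods: lineage fate, cell-cycle, karyotype and centrosome-cohort analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage fate, cell-cycle, karyotype and centrosome-cohort analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrofate)
```

`centrofate` packages the quantitative machinery used to study how
centrosome amplification shapes the response of epithelial ovarian cancer
cells to chemotherapy: single-cell lineage fate analysis of annotated
time-lapse movies, FUCCI cell-cycle analytics, single-cell karyotype
scores, the centrosome-to-nucleus-ratio (CNR) cohort analysis, and nuclear
focus counting. Because raw movies, single-cell sequencing runs and cohort
records are not desk-portable, each analysis is paired with a seeded
synthetic generator that reproduces the statistical structure the analysis
assumes; every quantitative claim the package makes is the output of those
analyses run on generated or hand-built inputs.

## Lineage model

A *lineage* is the tree of cells descending from one cell present at movie
start (the root, generation 1). Each tracked cell carries integer event
times in minutes -- birth, mitotic entry, end -- quantized to the
acquisition cadence (10-minute frames over a 72-hour movie by default), a
terminal *fate* (divided, died in interphase, died in mitosis, alive at
movie end), and, when it divided, a *mitotic phenotype*: bipolar division
with no, slight (one lagging chromosome, bridge or mis-alignment) or high
(multiple concurrent errors) chromosome mis-segregation; multipolar
division; cytokinesis failure; or mitotic slippage. Structural conventions,
enforced by `validate_lineages()`:

* Bipolar phenotypes produce exactly 2 daughters, multipolar at least 3,
  and cytokinesis failure / slippage exactly 1 successor record in the next
  generation (the continuing, now-binucleated or non-divided cell). Treating
  the continuing cell as next-generation progeny lets the
  mitosis-to-fate cross-tabulation handle all phenotype classes uniformly.
* Death in mitosis aborts the division: it is a fate with no phenotype and
  no progeny, and enters the phenotype spectrum as its own marginal class.
* Cells alive at movie end are an explicit right-censored fate, never a
  missing value; roots are birth-censored, so interphase lengths are only
  defined for non-root cells.
* Sub-frame events are disallowed: all times are multiples of the frame
  interval.

The three headline analyses follow the published workflow:
`lineage_fate_counts()` (cells per lineage adopting each fate, mean and SEM
across replicates when two or more are present, across lineages otherwise
-- the basis is reported), `generation_fate_percent()` (fate percentages
within one generation, censored cells in the denominator), and
`mitosis_fate_crosstab()` (progeny fate conditioned on the mother's mitotic
phenotype). Because the published bar widths are ambiguous about their
marginal basis, the crosstab reports phenotype frequencies both among
divisions and weighted by progeny. Condition comparisons use the tests the
original figure legends name: a two-sided Fisher exact test on pooled death
counts (cells, not lineages) and a Pearson chi-square on the phenotype
spectrum; multi-group post-hoc testing is left to standard routines.

## FUCCI phase analytics

FUCCI reporters distinguish G1 from S/G2; tracks are ordered phase
intervals (G1, S/G2, M) ending in division, death or movie end. Phase
classification from fluorescence is upstream: the module consumes
already-classified intervals. Conventions: a death at a phase boundary
belongs to the phase being *entered* (encoded as a zero-length terminal
segment -- a deterministic, testable tie rule; the source material
specifies none); phase-length statistics use only fully observed phases,
so generation-1 phases (birth-censored) and phases truncated by death or
movie end are excluded and counted; the start-phase analyses
(`entry_time_by_start_phase()`, `fate_by_start_phase()`) are restricted to
cells present at time 0, the one unambiguous reading of "phase at movie
start" for a branching population.

## Karyotype scores

Scores operate on called integer copy-number matrices over genomic bins
(0-based half-open coordinates; calling itself -- HMM or circular binary
segmentation -- is upstream and out of scope). With bin widths $w_b$,
calls $c_{b\ell}$ and euploid expectation $e_b$ (default 2 everywhere;
sex-chromosome conventions are configurable because the source states
none):

* **Aneuploidy score** per library: $\sum_b w_b\,|c_{b\ell}-e_b| \,/\,
  \sum_b w_b$; sample score: unweighted mean over libraries.
* **Heterogeneity score** per bin: the fraction of the $\binom{n}{2}$
  library pairs with discordant calls (magnitude ignored); sample score:
  bin-size-weighted mean over bins.

Curation mirrors the published pipeline: libraries are kept when two
segmentation algorithms agree on at least 90% of the genome
(`concordance_filter()`; weighting by bin size for consistency with the
scores, with an unweighted per-bin variant reported because the original
weighting is unstated) and when the mean read depth reaches 10 reads per
bin per chromosome copy (`depth_filter()`: total reads divided by the
summed copy number over bins).

## CNR, CART and survival

The CNR of a field is its centrosome count divided by its nucleus count;
the sample CNR is the unweighted mean over (typically 10) fields, the
convention matching per-field averaging in the source; pooled totals are
reported alongside. `cart_threshold()` performs the depth-1 classification
step: an exhaustive search over midpoints of consecutive sorted unique
marker values for the split minimizing total Gini impurity against the
binary 6-month relapse outcome, ties broken toward the smaller threshold,
low group defined as values at or below the cutoff. One cutoff, no pruning
or cross-validation -- exactly what a single reported threshold implies.
Which impurity the original cohort analysis used is unstated; Gini is the
canonical CART default. Kaplan-Meier curves and the two-group log-rank test
(the comparison test is unnamed in the source; log-rank is the stated
assumption here) are delegated to the `survival` package behind the module
interface, with independent hand product-limit and
observed-minus-expected oracles in the test suite. Spearman correlations
use average ranks with the large-sample t approximation. Months are the
canonical clinical time unit.

## Focus counting

DNA-damage foci are counted on z-projections (maximum intensity by
default, sum available; the source says only "z-projections") via the
h-maxima transform: grayscale morphological reconstruction by dilation of
`image - h` under `image` suppresses every local maximum whose dynamic is
below `h`; the surviving 8-connected regional maxima intersected with the
nucleus mask are the foci. Reconstruction uses the Vincent (1993) hybrid
raster/anti-raster algorithm with a FIFO queue, implemented in C++;
8-connectivity is the common spot-counting default. `h` has no default --
its value is unreported in the source and must be set relative to spot
amplitude and noise; for well-separated spots of amplitude $a$ over
background $b$ with noise $\sigma$, any $h \in (5\sigma,\; a-b-5\sigma)$
recovers the planted count exactly, a property the tests verify over
seeds. Nucleus masks are inputs; only a trivial threshold helper is
provided for fixtures.

## Synthetic generators: what they emulate, and what they do not

All generators are pure functions of a `simulation_config()`; one global
seed feeds deterministically derived sub-streams, so adding a generator
never perturbs another's output. Defaults echo the magnitudes reported for
this system -- they are illustrative study conditions, not ground truth:

* **Lineages**: a discrete-time branching process. Interphase lengths are
  lognormal around a 20-hour median (mitosis 40 min); mitotic phenotypes
  follow a categorical distribution that can switch after 24 h of
  simulated exposure, emulating high mis-segregation arising only after a
  full S phase under a DNA-damaging drug; per-daughter death probabilities
  are conditional on the mother's phenotype (defaults 0.12 bipolar-clean
  up to 0.5 multipolar); death times are uniform within the interphase;
  the movie truncates everything at 72 h.
* **FUCCI tracks**: cells start at time 0 inside G1 or S/G2 with occupancy
  proportional to the programmed durations (480/720/60 min); a
  configurable S/G2 extension applies to cells that were in G1 at time 0
  (those traverse S phase under drug); deaths are placed in a phase drawn
  from configured weights (default 80% S/G2), uniformly within it.
* **Copy numbers**: every chromosome of every cell independently gains or
  loses one copy per division with the mis-segregation probability,
  floored at zero, over a configurable number of generations; bins inherit
  their chromosome's copy number.
* **Cohort**: true CNRs from a two-component normal mixture either side of
  1.45 (38% high, the published 33/88 split); Poisson field counts;
  exponential relapse and survival times with a configurable hazard ratio
  between CNR groups and independent censoring.
* **Spot images**: Gaussian spots (amplitude 80, background 10, noise sd
  3, sigma 2 px) on a jittered grid guaranteeing more than 4 sigma of
  separation, three z-slices with weighted spot intensity, integer-rounded
  counts.

What the generators do *not* emulate -- and therefore what passing tests do
not show about real data: segmentation and tracking errors, uneven
illumination and bleaching, mis-classified phases or phenotypes,
GC/mappability artefacts in copy-number calls, cohort covariate structure
(stage, treatment heterogeneity) and non-exponential hazards. The tests
demonstrate that the estimators recover what the data-generating process
put in, at the stated sample sizes, not that the upstream measurement
process is faithful.

## Numerical choices and verification conditions

* Problem sizes were chosen so the whole suite runs in about a minute:
  200 random matrices (up to 8 libraries x 30 bins) for the score oracles;
  500 random 2x2 tables for the exact-test oracle; ~2,300 fully observed
  divisions for death-probability recovery; 4,000 FUCCI tracks for the
  extension recovery (the median of the discrete uniform start offsets has
  a ~10-minute standard error there, comfortably inside the 3-frame
  tolerance); 200 replicates for log-rank size and power; 100 seeded
  cohorts for CART recovery; 20 seeds x 3 h-values for focus recovery.
* Death-probability recovery uses one fully observed division round
  (fixed 2,130-min interphase in a 4,320-min movie) and restricts the
  crosstab to generation-1 mothers: in an open-ended branching movie the
  last generation is always right-censored, which would bias progeny death
  proportions downward regardless of implementation correctness -- the
  restriction mirrors the first-mitosis analysis of the original workflow.
* The CART recovery benchmark uses a deliberately well-separated cohort
  (component sd 0.05, 100 nuclei per field, near-deterministic 6-month
  outcome contrast). Two structural effects make weaker contrasts fail a
  changepoint-separation check even with a correct implementation: the
  order statistics of the two measured-CNR components overlap at realistic
  noise, and a depth-1 Gini split provably prefers to move a minority-
  outcome boundary sample out of a majority-event child (doing so always
  lowers total impurity when that child's event prevalence exceeds 1/2).
  The package default cohort keeps the weaker, paper-like contrast.
* Ties and degenerate inputs: Fisher tables with a zero margin report
  p = 1 with a degenerate flag; log-rank with no events likewise; the CART
  search refuses single-class outcomes; zero-nuclei fields are excluded
  from the CNR with a count; constant images contain no foci for any
  positive h.
* Regional maxima are extracted with a reconstruction at a relative
  dynamic of 1e-9 of the image range, far below any meaningful intensity
  quantum but non-zero so plateaus merge correctly.

## Known limitations

The package analyzes annotated events; it performs no segmentation,
tracking, phase classification, copy-number calling or centrosome
detection. SEM-across-replicates requires replicate labels and falls back
to across-lineage dispersion with only one replicate. The log-rank test is
asymptotic; for very small cohorts an exact or permutation comparison
would be preferable. The h parameter of focus counting is data-dependent
by design and must be chosen by the analyst.

## A worked pass through the pipeline

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 7, lineage = list(n_lineages = 40))
tab <- simulate_lineages(cfg)
lineage_fate_counts(tab)$summary
mitosis_fate_crosstab(tab, mother_generation = 1)

coh <- simulate_cohort(simulation_config(seed = 7))
cnr <- compute_cnr(coh$fields)
cut <- cart_threshold(cnr$cnr, coh$cohort$relapse_within_6mo)
grp <- classify_cnr(cnr$cnr, cut$threshold)
logrank(coh$cohort$os_months[grp == "low"], coh$cohort$os_event[grp == "low"],
        coh$cohort$os_months[grp == "high"], coh$cohort$os_event[grp == "high"])
```
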