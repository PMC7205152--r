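---
title: "Inferring tumor purity and absolute copy numbers from binned read depths"
author: "puracn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tumor purity and absolute copy numbers from binned read depths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

A sequenced tumor sample is a mixture: a fraction $\alpha$ (the *tumor
purity*) of tumor cells and $1-\alpha$ of normal cells.  A somatic copy-number
variant present in the tumor cells therefore shows a *diluted* read-depth (RD)
signal.  Writing $\bar r$ for the genome-wide mean RD — attributed to the
diploid, copy-number-neutral state — a region carrying $c$ tumor copies has
expected observed RD

$$E[R] \;=\; \bar r\,\frac{\alpha c + 2(1-\alpha)}{2}.$$

puracn inverts this mixture using only the **loss** regions.  Losses are
special because they take exactly two states — heterozygous ($c=1$) and
homozygous ($c=0$) — so no prior genotyping is needed.  For a candidate
$\alpha$ the observed loss RDs $R$ are deconvolved to pure-tumor
("absolute") RDs

$$Q = \frac{R - (1-\alpha)\,\bar r}{\alpha},$$

split into the two states by two-means clustering (labels $B \in \{0,1\}$,
lower-mean group $=0=$ homozygous), mapped back to model expectations
$E = \alpha\bar r B/2 + (1-\alpha)\bar r$, and scored by the mean absolute
deviation $d(\alpha) = \frac1n\sum_i |E_i - R_i|$.  An exhaustive grid
$\alpha \in \{0.05, 0.06, \dots, 0.95\}$ is scanned and the smallest
$\alpha$ attaining the minimal deviation is the estimate $\hat\alpha$
(`gridSearchPurity()`).  Given $\hat\alpha$, *every* CNV region (losses and
gains) is converted to an absolute copy number
$\mathrm{CN} = 2\,Q/\bar r$ with $Q$ clipped at zero
(`absoluteCopyNumber()`); tumor ploidy is assumed to be 2 throughout.

Key assumptions, stated plainly:

* $\bar r$ corresponds to the normal diploid state.  This holds when CNVs
  occupy a small genome fraction and both directions of change occur; the
  default keeps $\bar r$ as the plain unmasked-bin mean, and
  `runPipeline(excludeCNVFromRBar = TRUE)` recomputes it outside the called
  regions when aberrations are extensive.
* At least two loss regions exist, ideally of both states.  If the sample
  truly contains only heterozygous losses the two-cluster model is
  misspecified; the full deviation curve is always reported
  (`deviations()`) so flat or ambiguous minima can be inspected — the
  package does not guess.
* Observed RD is taken *per region* (the mean corrected RD of member
  bins), and $n$ in $d(\alpha)$ counts regions, not bins.

# The deviation objective, exactly once

The two-means step inside the grid search is solved *exactly*: in one
dimension the optimal two-cluster partition is a threshold in sorted order,
so all $n-1$ threshold partitions are scanned with prefix sums and the
within-cluster sum-of-squares minimum is found deterministically.  Any
converged Lloyd K-means solution can only match, never beat, this optimum,
and the result does not depend on a random initialization — important
because the classification runs 91 times per sample inside the grid.  Ties
across grid points are broken toward the smallest $\alpha$; ties in the
threshold scan toward the leftmost optimal split.  If a candidate $\alpha$
collapses all $Q$ onto one value, the no-separation rule labels every
region heterozygous and that candidate is still scored, so degenerate
candidates are penalized by the curve itself rather than erroring out.

# From BAM to profile

`binReadCounts()` divides the genome into non-overlapping bins (default
1000 bp) and assigns each retained read to exactly one bin by its leftmost
mapped position; secondary, supplementary, duplicate and unmapped records
are excluded.  This makes binning conservative: per-bin counts sum to the
number of retained alignments.  Bins whose reference window is more than
half 'N' are masked out of all statistics (`maskNBins()`; filling with the
mean is available as an option, masking is the default because it fabricates
no signal).  GC bias is corrected by the standard median-ratio approach:
each bin is rescaled by (global median RD) / (median RD of its 1 %-wide GC
stratum); strata with fewer than 20 unmasked bins borrow the nearest
populated stratum's factor so sparse GC extremes are not rescaled by an
unstable median.  Coordinates are 0-based half-open on disk (TSV/BED) and
1-based inside `GRanges`.

# The anomaly-score detector

CNV bins are flagged by a one-dimensional isolation forest: 256 trees, each
grown on 256 bins subsampled without replacement, splitting at uniform
random points of the RD value.  A bin isolated after a short average path —
an RD far from the bulk in *either* direction — scores high:
$s = 2^{-E[h]/c(\psi)}$.  Because the feature is 1-D, each fitted tree is a
partition of the real line, so scoring is a `findInterval()` lookup per
tree and the whole genome is scored in well under a second.

The raw scores are smoothed by exact 1-D total-variation denoising (the
proximal operator $\min_u \tfrac12\|u-s\|^2 + \lambda\sum|u_{i+1}-u_i|$,
solved by Condat's direct algorithm, per chromosome).  The penalty matters:

* TV shrinks an *isolated* spike by $2\lambda$ but a segment of length $L$
  only by $2\lambda/L$.  The default $\lambda = 2\,\mathrm{sd}(s)$ was
  calibrated on the synthetic study conditions so that single-bin noise
  excursions are absorbed (at $0.3\,\mathrm{sd}$ a 40,000-bin profile
  yields hundreds of one-bin false calls at level 0.01, and those false
  "losses" with RD just under $\bar r$ visibly bias the purity estimate),
  while 20–100-bin aberrant segments lose almost none of their height.
  Substantially larger penalties start flattening weak heterozygous-loss
  segments at low purity into the background, so 2 sd is a deliberate
  middle ground; the parameter is exposed as `lam`.

Smoothed scores are tested against a Gamma distribution fitted by the
method of moments (shape $m^2/v$, scale $v/m$), upper tail only — high
anomaly means CNV; direction is decided later from the RD itself.  A bin is
flagged when $p <$ `level` (default 0.01, no multiple-testing correction;
Benjamini–Hochberg is available via `adjust = "BH"`).  Two reconstruction
decisions around the threshold:

* **Hysteresis region growing** (`levelExtend`, default $10\times$ level):
  a contiguous run of bins with $p < 0.1$ is kept only if it contains at
  least one $p < 0.01$ seed bin.  Weak segments — heterozygous losses at
  low purity sit only $\sim\!1.5$ Poisson SDs below the bulk — have
  smoothed-score plateaus that straddle the primary threshold; without the
  relaxed extension they fragment into slivers that fail reciprocal-overlap
  matching and dilute region means.  Isolated noise lacks a seed bin and is
  unaffected, so the null false-call rate stays at the primary level.
* **Merging** (`mergeCalls()`): maximal runs of consecutively flagged
  unmasked bins on one chromosome become one region; direction is `loss`
  or `gain` by comparing the region's mean corrected RD to $\bar r$.

The detector is deliberately replaceable: `loadExternalCalls()` ingests any
3+-column BED and attaches observed RDs from the profile, after which
purity and copy-number stages proceed identically.

# What the simulator emulates — and what it does not

`simulateProfile()` generates admixed profiles directly at the binned-RD
level: per-bin counts are Poisson (or negative-binomial for
over-dispersion stress tests) around the mixture mean above.  The default
study conditions are 40,000 bins of 1 kb (about one chromosome 21 at
10× coverage with 100 bp reads, i.e. base RD 100 per bin) and 25 planted
segments of 20–100 bins: five each at copy number 0, 1, 4, 5 and 8, placed
in separate genome blocks so both loss states always exist.  An optional
smooth sinusoidal GC bias exercises the correction step against a known
truth.  RD-level simulation preserves exactly the statistical structure the
purity and copy-number models consume, which is what makes the round-trip
testable; it does *not* emulate read-level artifacts (mappability,
alignment errors, GC effects at read granularity), real breakpoint
micro-structure, replication-timing waves, or intra-tumor heterogeneity
(a single clone at purity $\alpha$ is assumed).  Passing the synthetic
study therefore demonstrates correctness of the inference machinery under
its stated model, not robustness to every artifact of real libraries.

Validation scale: the replicated study used by the package's acceptance
checks runs 10 replicates at each purity 0.2–0.8 (step 0.1) at the sizes
above — chosen as the smallest design in which the per-level mean purity
error and aggregate copy-number accuracy are stable — and completes in a
couple of minutes on one core.  On these conditions the mean
$|\hat\alpha - \alpha|$ per level is about 0.01–0.02 and > 95 % of planted
segments at $\alpha \ge 0.3$ round-trip to their exact integer copy
number.  The residual purity bias is dominated by $\bar r$ inflation from
the planted gains (about +1.5 % at $\alpha = 0.5$), which
`excludeCNVFromRBar` removes.

# Numerical choices and edge cases

* Purity grid ties → smallest $\alpha$; grid values rounded to 10 decimals
  so `seq()` drift never misses an endpoint.
* $Q$ may be negative during clustering (clipping there would destroy the
  separation that identifies homozygous losses); it is clipped at zero only
  for copy-number reporting.
* Copy numbers are rounded half-up and floored at zero; both `cn_real` and
  `cn_int` are reported.
* Gamma fitting with zero-variance scores warns and calls nothing; scores
  $\le 0$ are shifted just above zero before fitting.
* An all-zero profile is an error (`meanRD()` refuses a non-positive mean,
  which the deconvolution would divide by).
* Fewer bins than the forest subsample reduces the subsample with a
  warning; identical RDs everywhere give every bin score 0.5 and no calls.
* All randomness (forest subsampling and splits, simulation noise and
  layout) flows from explicit integer seeds; a fixed seed reproduces every
  output file byte-for-byte.

# Known limitations

* Ploidy is fixed at 2; near-triploid tumors bias all copy numbers and the
  purity estimate.  Joint purity–ploidy search is out of scope.
* No use of allele fractions (BAF) or SNVs; the estimate rests entirely on
  RD, so a genome with very few losses (or losses of only one state) is
  intrinsically hard — inspect the deviation curve.
* The detector reconstructs the published anomaly-score design at the
  level of its summary (isolation forest → TV → Gamma tail); it does not
  claim fidelity to the original implementation's internals, and
  breakpoint placement is limited to bin resolution.
* Single-sample mode only: no tumor–normal paired normalization, no
  mappability correction, no multi-sample segmentation.
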