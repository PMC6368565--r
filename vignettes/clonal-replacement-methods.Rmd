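---
title: "Quantifying intra-tumor heterogeneity and clonal replacement under neoadjuvant therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-tumor heterogeneity and clonal replacement under neoadjuvant therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalshift)
```

## The problem

Breast tumors sampled in several regions before and after neoadjuvant
therapy can show a striking pattern: a cluster of mutations clonal in every
post-treatment region that was absent or rare in the pre-treatment biopsy.
Two mechanisms can produce it. Under *clonal replacement*, a resistant
subclone survives therapy and sweeps the residual tumor. Under *geographic
killing*, treatment merely eliminates most of a spatially heterogeneous
tumor, and the surviving corner happens to carry a private clone — no
treatment-driven selection required. `clonalshift` implements the
statistics and the two simulation models needed to tell these apart, plus
the downstream inferences: how big the resistant clone must have been
before treatment, and how fast resistance-conferring aberrations must
arise.

## Heterogeneity statistics

All statistics operate on a `mutation_table`: a mutation x region matrix of
cancer cell fractions (CCFs) with read support, one region tagged `pre` and
the rest `post`. CCFs come from variant allele fractions adjusted for
purity and local copy number (`ccf_from_vaf()`); on the simulated diploid,
CNA-free genomes CCF is simply twice the VAF.

**HFR** (high-frequency regional) asks how often a mutation that looks
clonal in one region (CCF > 0.5) is absent or rare (CCF < 0.1) in another:
with `R1`, `R2` the directional counts and `C` the mutations clonal in
both, `HFR = (R1/(R1+C) + R2/(R2+C))/2`. A directional term with an empty
denominator contributes 0. Because only drastic CCF differences count, HFR
is robust to moderate purity and coverage differences between samples.

**tHFR** transposes the idea to time: of the mutations clonal in *all*
post-treatment regions, the fraction that was rare in the single
pre-treatment region, `tR/(tR + tC)`. When cases differ in how many post
regions were sequenced, tHFR is averaged over all subsets of a fixed size
(`thfr(..., n_post =)`) so values are comparable.

**Fst** uses Hudson's depth-corrected ratio-of-sums estimator on subclonal
SNVs (CCF < 0.5 in at least one of the two regions): per SNV the numerator
term is $(f_a-f_b)^2 - \frac{f_a(1-f_a)}{d_a-1} - \frac{f_b(1-f_b)}{d_b-1}$
and the denominator term $f_a(1-f_b) + f_b(1-f_a)$; sums are taken before
the ratio. The sampling correction makes the estimator unbiased around zero
for identical regions, at the price of slightly negative estimates, which
we report unclipped. SNVs with depth <= 1 are excluded (the correction is
undefined); SNVs with discordant loss of heterozygosity should be masked by
the caller (`loh_mask`), as LOH calling is upstream of this package.

Mutation timing (`classify_timing()`) is rule-based: truncal (mean CCF >
0.6 and > 0.25 everywhere), else post-only (CCF < 0.1 pre-treatment), else
subclonal (pre CCF < 0.4, or absent in some post region). Where rules
overlap, the more specific temporal statement wins: a mutation absent
pre-treatment *and* absent in one post region is post-only. Read filters
(depth >= 20 in every sample, >= 4 variant reads in at least one) are
applied before every statistic, matching the calling criteria used for
patient tumors.

```{r stats-example}
set.seed(7)
case <- generate_case(planted_architecture("clonal_replacement"))
thfr(case$table)$thfr
table(classify_timing(case$table)$label)
```

## The spatial deme model

Virtual tumors grow as demes (well-mixed gland-like subpopulations) on a
3D lattice. A deme fills to its carrying capacity through a
discrete-generation branching update — each cell divides with probability
$b'/(b'+d)$, else dies, with $b' = b(1+s)^k$ for a cell carrying $k$
driver mutations — then fissions: the deme splits binomially into an
adjacent empty lattice site. Demes boxed in at capacity turn quiescent, so
growth is peripherally dominated, consistent with the elevated
proliferation of peripheral tumor cells. Mutations arise
Poisson(0.6)/division under infinite sites; each is a driver with
probability $10^{-5}$. Defaults: birth 0.55, death 0.45, 50 truncal SNVs
carried by the founding cell, selection coefficients on the grid
{0, 0.05, 0.1, 0.2, 0.4, 0.5} and deme sizes {1000, 5000, 10000, 50000}.

Open details the model statement leaves unspecified were fixed once: the
lattice neighborhood is 3D Moore (26 neighbors) with a uniform random
choice among empty sites; a regional sample is the contiguous neighborhood
(nearest occupied demes) of one focal deme; within-deme updates are
discrete generations rather than an event-driven exact simulation, which
is adequate because only deme-level composition is observed. The
implementation is in C++ (a genotype tree with contiguous mutation-id
blocks; per-deme genotype counts), driven by R's RNG so `set.seed()` makes
whole tumors reproducible.

Sequencing is emulated per regional sample: depth ~ Poisson(100), variant
reads ~ Binomial(depth, fraction/2), CCF = 2 x VAF clipped to [0, 1.5],
then the same read filters as for patients. Sampling schemes mirror the
study designs: `local` (one octant), `distant` (distinct octants),
`all_octants` (a 20-region panel), `opposite_octant_pre_post` (pre sample
from one octant, posts from the opposite octant — the conservative
geographic-killing configuration), and `opposite_quadrants_post` (posts
split between opposing quadrants, for cases whose block layout is known).

### What scale buys and costs

Full-scale virtual tumors have $10^9$ cells. The package is routinely run
at $10^6$–$10^7$ cells with regional samples scaled as
`target_cells/1000`. Between-region divergence in this model accumulates
with the number of serial deme generations from core to periphery — i.e.
with tumor radius — and driver sweeps need many residual doublings to
spread spatially. Both are curtailed in scaled-down tumors, so
selection-cohort statistics (HFR near 0.35 distant / 0.27 local at full
scale; reclassification gains of 31–47%) are systematically smaller at
desk scale, while the neutral baseline (HFR about 0.03) and all
*relative* orderings (selection > neutral, distant > local, smaller demes
> larger) are preserved. Tests and the acceptance script use 30–50 tumors
per cohort at $10^6$–$4\times10^6$ cells; these sizes are stated where
used and were chosen as the largest this package's test harness can
afford routinely.

## tHFR null distributions and ABC

To test an observed tHFR against geographic killing alone,
`build_thfr_null()` replays a pre/post sampling scheme on *untreated*
virtual tumors: one pre sample from an octant, post samples from the
opposite octant (or the quadrant-aware variant), tHFR averaged over post
subsets of the case's size. The percentile of the observed value in this
empirical null (`test_clonal_replacement()`; strictly-less-than
convention, ties below) quantifies how often spatial heterogeneity alone
produces as much apparent clonal change; the default verdict cutoff is the
90th percentile, the weakest call made in the cohort analyses. The
null-building grid excludes neutral growth and deme size 50,000, which are
inconsistent with the heterogeneity of primary breast tumors.

`abc_infer()` is deliberately plain rejection ABC: summary statistics are
standardized, the closest 5% of simulations by Euclidean distance
accepted, acceptance counts per parameter value reported as posterior
mass. The default statistic panel — case Fst, mean pairwise HFR, fraction
of mutations subclonal somewhere, mean pairwise Kolmogorov–Smirnov
distance between regional CCF distributions — is a pragmatic
reconstruction of the heterogeneity-metric panels used with such
simulators (the original panel is defined only in external code), and the
set is pluggable; results should be read accordingly.

## The branching treatment model

Treatment response is modeled without space: a continuous-time birth-death
process with division rate $b = 0.15$/day and death rate $d = 0.13$/day
(2%/day net growth), grown from one sensitive cell to $10^{10}$ cells,
then treated for 150 days during which sensitive cells die at
$d' \in \{0.16, 0.2, 0.25\}$, resistant cells keep their rates, and no new
aberrations arise. Resistance-conferring aberrations arise at effective
rate $\mu$ per division ($\mu$ = aberration rate per site x number of
resistance sites); each founds a distinct clone.

Simulating $10^{10}$ cells per event is infeasible, so the engine is the
standard hybrid: the sensitive bulk is stochastic (exact birth-death
transition sampling: binomial surviving lineages plus negative-binomial
offspring) below $10^3$ cells and deterministic above; clones alive at
detection are drawn by thinning the founding Poisson process (intensity
$\mu b N(t)$) with the exact alive-at-detection probability, their sizes
from the exact conditioned geometric law; the earliest 200 clones — the
largest, in expectation — are tracked individually and later clones enter
as an aggregated compartment equal to their exact expectation. Clone
founding during the sub-threshold era is seeded from the recorded
stochastic trajectory. During treatment every compartment follows the
exact transition law, switching to deterministic updates above $2^{30}$
cells where relative fluctuations are negligible; the declining sensitive
bulk crosses back into the stochastic regime so that pathologic complete
response (pCR), which hinges on extinction of the last $10^4$ cells, keeps
its stochasticity. A type-level Gillespie simulator (exact, per event) is
kept in the package purely as a cross-check and agrees with the hybrid
engine on small instances.

Outcomes follow fixed thresholds: pCR below $10^4$ residual cells; else
sensitive residual disease, clonal replacement, or polyclonal resistance
by whether sensitive cells, one resistant clone, or neither holds >= 80%
of the residual. One empirical finding from building this model is worth
stating plainly: with *every* resistant clone counted — the outcome
definitions as stated — single-clone dominance of the residual occurs in
only ~1–3% of runs across $\mu \in [10^{-6}, 10^{-3}]$, because clones
founded continuously up to detection spread the resistant mass across a
heavy-tailed (exponent-1) size spectrum. Restricting attention to the
earliest-born few clones (as visualizations of such models often do)
yields ~10% instead. The package implements the stated definition; the
tests record the measured rate.

`infer_mu_interval()` inverts the model: $\mu$ is drawn on a log-uniform
grid over $[10^{-10}, 10^{-2}]$ (the grid is the prior), runs qualify when
they match the observed pattern — clonal replacement with shrinkage to
10–50% of the pre-treatment size — and the 5th–95th percentile of
qualifying $\mu$ values is reported per $d'$ and pooled across the three
$d'$ values (the pooled interval is the headline; per-$d'$ intervals are
also returned since the pooling choice is a convention).

## Resistant-clone size back-calculation

`resistant_fraction_interval()` assumes the resistant clone grew
exponentially through therapy at a net rate between 0.65%/day and
2.8%/day, occupied 90–100% of the residual tumor, and that volumetric
measurements carry ±25% uncertainty (applied independently to the pre and
post measurement by default; a correlated mode is provided since the
uncertainty statement does not fix this). With $10^9$ cells/cm³, the
clone's pre-treatment fraction is monotone in every input, so the feasible
interval is attained on the corner grid, which is enumerated exactly.

```{r clone-size}
resistant_fraction_interval(pre_volume_cm3 = 14, post_volume_cm3 = 1.8,
                            treatment_days = 150)
```

## The synthetic-data generator

`generate_case()` emulates the cohort layout — one pre-treatment region
plus several post-treatment regions, tens to hundreds of SNVs — with a
planted architecture: truncal mutations at CCF 1 everywhere, regional
subclones, and optionally a replacing clone clonal post and rare pre (the
P5-like variant plants it at CCF ~0.02–0.05 pre-treatment, detectable in
hindsight). Reads are binomial at the declared depth and purity; truth
labels ship in a sidecar so tests never re-derive them from noisy data. It
emulates read sampling and purity dilution but *not* FFPE artifacts,
copy-number change, or realistic mutational spectra — statistics passing
on synthetic cases demonstrate correct computation and threshold behavior,
not robustness to artifact-laden real data, whose filtering happens
upstream.

## Numerical conventions and limitations

* Coordinates are 0-based half-open internally; BED on output.
* "Absent" is CCF < 0.1 throughout; there is no separate zero-read class.
* Non-estimable statistics (empty denominators) return `NA` sentinels and
  are skipped by case-level averages; HFR's empty-denominator terms
  contribute 0 by convention.
* Multiplicity in `ccf_from_vaf()` defaults to 1 when unknown.
* The Fst subclonal-inclusion rule is applied per region pair.
* The spatial model has no cell migration, no deme death, and no treatment;
  treatment lives entirely in the (non-spatial) branching model.
* Scaled-down spatial cohorts underestimate absolute selection-driven
  heterogeneity (see above); comparisons across conditions remain valid.
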