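---
title: "Quantifying missing-data effects in mitogenome bycatch analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying missing-data effects in mitogenome bycatch analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bycatchsim)
```

## The problem

Targeted sequence capture experiments yield off-target ("bycatch") reads,
and for insects these often assemble into partial mitochondrial genomes.
Such data are patchy: each sample has a *coverage breadth* — the proportion
of reference positions with a called base — anywhere from a few percent to
essentially complete. Before trusting population-genetic or phylodynamic
conclusions drawn from bycatch, one wants to know how coverage breadth
distorts them.

`bycatchsim` builds that sensitivity analysis as a fully synthetic,
seed-reproducible pipeline for a two-subspecies system modelled on a
globally distributed pest moth: an Australasian deme ("conferta") and a
cosmopolitan deme ("armigera"), sampled heterochronously over roughly a
century, with mitogenome-scale sequences (~15.4 kb) and bycatch-style
missingness. Every downstream inference — discriminant analysis of
population structure, coalescent skyline reconstruction, monophyly support
— can then be compared across coverage-breadth thresholds against known
truth.

## The generative model

### Demography and genealogy

Time is measured in calendar years throughout, and effective size is
everywhere the compound
$\nu = N_e \times \text{generation time (years)}$,
so the coalescent rate for $k$ lineages in a deme is
$k(k-1)/(2\nu_{\text{deme}}(t))$
per year and no separate generation-time parameter is needed (none is
identifiable from this design). `simulate_genealogy()` runs the two-deme
structured coalescent backwards from the sampling dates: tips enter at
their collection dates, lineages coalesce only within a deme, and switch
demes at a per-lineage migration rate. Each deme's $\nu$ is either
constant or *growth-then-plateau*: exponential growth forward in time up
to a plateau year, constant afterwards — the trajectory shape typical of
an expanding pest that saturates around the turn of the twentieth century.
Time-varying rates are simulated exactly by inverting the cumulative
coalescent intensity (time rescaling); into the past the pre-plateau
$\nu$ shrinks geometrically, so the intensity diverges and every
simulation terminates.

One boundary case needs a convention: with `migration_rate = 0` and both
demes present, the two deme ancestors can never meet. They are joined by a
pairwise coalescent in an ancestral pool whose constant $\nu$ is the mean
of the two plateau values. This keeps zero-migration genealogies finite
and reciprocally monophyletic, which the tests rely on.

### Sequences

`simulate_sequences()` evolves sites down the genealogy under GTR with
discrete-gamma rate variation: the root sequence is drawn from the
stationary base frequencies, each site gets one of `n_categories`
(default 4) equal-probability mean-of-quantile rate multipliers, and each
branch applies $\exp(Q \cdot \text{clock} \cdot r_{\text{site}} \cdot \Delta t)$
through a symmetric eigendecomposition of the reversible rate matrix. The
default parameterization uses AT-rich base frequencies (0.35, 0.15, 0.10,
0.40), a transition/transversion-biased exchangeability vector, and a
clock of $10^{-6}$ substitutions/site/year — the mean of the gamma(10,
$10^{-7}$) rate prior used in the inference stage, in the range reported
for insect mitochondrial DNA.

### Bycatch masking

`apply_bycatch_mask()` converts a complete alignment into patchy data.
Missing positions are laid down as contiguous runs with geometric lengths
(default mean 300 bp) at uniform random starts, wrapping around the end
of the alignment because the mitogenome is circular, until each sample's
realized coverage is within ±0.02 of its target; the last run is
truncated so the tolerance always holds exactly. The per-sample targets
may be a constant or a draw — the pipeline default `runif(0.05, 1)`
emulates the 5–100% spread seen in real bycatch. Masking never alters a
retained character, so coverage effects are attributable to missingness
alone.

What the generator does *not* emulate: read-level errors, alignment
error, indels, recombination, contamination, or any correlation between a
sample's age and its coverage. Passing tests therefore show robustness to
*missingness structure*, not to every pathology of real museum data.

## The inference stages

### Coverage filtering

`coverage_proportion()` measures breadth; `threshold_subsets()` builds
nested datasets retaining samples with coverage ≥ each threshold
(inclusive, matching the "at least 65%" convention of marker-window
filters), with the default grid of eleven thresholds from 5% to 65%.
`window_filter()` implements the marker-style rule (e.g. at least 65%
coverage of the first 653 bp). `linear_fit()` is the shared OLS helper,
with $R^2$ defined as 0 for a constant response so batch reports never
propagate NaN.

### DAPC

`encode_alignment()` keeps sites polymorphic among called bases, encodes
each non-major allele as a 0/1 indicator column (tri-allelic sites expand
to two columns; the major allele is the most frequent among called bases,
ties broken alphabetically), and mean-imputes missing cells with the
column mean of observed values. Mean imputation is deterministic and
standard for genotype PCA — and it is exactly the channel through which
missingness acts on the discriminant analysis: a sample with little data
is pulled toward the global centroid, between the cluster centroids.

`pca_reduce()` centers and eigendecomposes, retaining
`ceiling(0.30 * rank)` axes by default — the "first 30% of principal
components" rule, read as a count of axes (the adegenet idiom), not a
variance fraction; the fraction is exposed as an argument for the other
reading. `dapc_fit()` computes the single two-group discriminant axis
maximizing between- over within-group variance, and converts projections
to memberships with a one-dimensional Gaussian model per group (group
means, pooled variance, equal priors). This posterior rule is declared
rather than claimed identical to any reference implementation; on
separated groups it saturates the same way. `classify_admixed()` flags a
sample when its assigned-cluster probability lies in the closed interval
[0.01, 0.99], and `admixture_vs_composition()` regresses the admixed
proportion on the minority-cluster fraction across datasets.

### Phylodynamics

`coalescent_loglik()` is the standard heterochronous coalescent density
for a piecewise-constant $\nu(t)$; sampling events change the lineage
count without a density term. `classic_skyline()` is its deterministic
per-interval MLE companion, accumulating $k(k-1)\Delta t/2$ between
successive coalescences. A note on summarizing it: individual epoch
estimates are approximately exponential around the truth, so their
*unweighted* harmonic mean is badly biased low; the duration-weighted
harmonic mean equals $\text{TMRCA}/(2(1-1/n))$ for isochronous tips and
recovers $\nu$, and that is the summary used in the tests.

`skyline_mcmc()` samples per-group $\nu$ on a *fixed* genealogy:
coalescent intervals are grouped contiguously with near-equal event
counts (default `min(10, events/2)` groups), the most recent group gets
an exponential prior with mean 10,000 years, and each older group an
exponential prior centred on its younger neighbour's current value — the
chained smoothing of Bayesian skyline models. Proposals are
multiplicative log-normal, with step sizes adapted toward ~30%
acceptance during the burnin fraction only, so the post-burnin chain is a
valid fixed-kernel sampler. Burnin (default 10%) applies to the recorded
trace, and the effective sample size of every group (initial
positive-sequence estimator, `ess()`) is compared against 200 with a
warning. The desk-scale defaults ($10^5$ steps, thinning 50) keep runs in
seconds; the full-scale settings ($2\times10^8$ / $10^5$) are plain
arguments. Likelihood-off runs sample the prior only and serve as the
dates-only control, alongside `simulate_dates_only_trees()`, which draws
$\nu$ from its prior and simulates genealogies on the observed dates.

Replacing the joint Bayesian tree-and-parameter inference with
`estimate_tree()` (fixed genealogy downstream) is the central scale
compromise: JC-corrected pairwise-deletion distances, UPGMA, node heights
converted to years by the clock rate, tips shifted to their collection
dates with deterministic zero-length-branch repair (a parent is clamped
to its oldest child). Saturated comparisons ($\hat p \ge 0.7$) take a
fixed cap distance, and with `min_overlap = 0` a pair sharing no sites
takes the cap too — no overlap carries no information, so such pairs are
treated as maximally diverged rather than rejected. The default floor of
50 shared sites instead raises an error naming the offending pair.

### Monophyly

`largest_monophyletic_proportion()` scans all clades of a rooted tree in
one post-order pass and returns the size of the largest clade containing
only focal-labelled tips, divided by the number of focal tips (1 =
complete monophyly; a single tip always counts, so the floor is
$1/|\text{labels}|$). Branch lengths and child order are irrelevant;
unrooted trees are rejected rather than silently rooted.
`monophyly_distribution()` evaluates it over a tree set, subsampling 1000
trees by default (without replacement; a flag gives bootstrap
semantics).

## The pipeline

`run_experiment()` chains everything: simulate → mask → threshold → per
threshold (DAPC, tree + skyline, monophyly vs dates-only control) →
cross-threshold summaries (admixture-vs-composition regression,
root-height-by-coverage table) → a JSON index of all outputs. Every stage
derives its seed from the root seed and a stage label, so identical
configurations give byte-identical outputs; a failing stage is logged by
name and the remaining datasets still run.

## Numerical choices and degenerate inputs

* All coalescent and MCMC arithmetic is in log space where underflow is
  possible; dates-only runs in particular never form raw likelihoods.
* Tied event times (zero-length branches from the tip-date repair)
  produce degenerate skyline epochs; these are floored at machine epsilon
  and flagged, and epoch boundaries are perturbed by 1 ns to keep strict
  ordering.
* A constant MCMC trace has ESS 1 by convention; the ESS estimate is
  capped at the trace length.
* Empty threshold datasets are returned as `NULL` with a warning, not an
  error, so batch runs continue.
* The admixture interval and threshold comparisons are closed (inclusive)
  ranges.

## Problem sizes used in the tests

The shipped tests and the acceptance script run everything at desk scale,
chosen once as sizes a laptop handles in minutes: calibration checks use
2000 replicate genealogies of 2–10 tips; the DAPC checks use 40–80
samples and 4 kb alignments (a few thousand variable columns); the
coverage-degradation experiment uses 10 simulation seeds by 6 coverage
levels; the tree-distortion experiment uses 60 samples at full
mitogenome length (15,390 bp) with deep divergence
($\nu = 5000$, zero migration, clock $10^{-5}$) — the regime in which
overlap starvation between low-coverage samples visibly inflates
distance estimates. At shallow, fully realistic divergence the UPGMA root
is dominated by sampling noise and the distortion, while present in the
distances, is not reliably visible in a single root-height comparison;
the vignette flags this as a limitation of the distance-based stand-in
rather than a property of the Bayesian analyses it replaces.

## Known limitations

* The discriminant membership model is a declared simplification; absolute
  admixture proportions depend on it, though coverage *trends* do not.
* The fixed-genealogy skyline ignores tree uncertainty, so its credible
  intervals are narrower than a joint analysis would give.
* The migration rate between the demes is a free parameter (the system's
  true value is unknown); defaults keep it small and the zero-migration
  case exact.
* UPGMA assumes clock-like divergence; strongly rate-variable data would
  distort the dated trees beyond what is modelled here.
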