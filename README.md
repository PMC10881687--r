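# bycatchsim

Mitochondrial genomes assembled from off-target ("bycatch") reads of
targeted capture experiments are a cheap source of population-genetic
data — but they are patchy. Each sample covers only a fraction of the
reference (its *coverage breadth*), and analyses run on such data can be
distorted in ways that look like biology: inflated admixture signal,
spuriously old demographic histories, weakened clade support.

`bycatchsim` is an R package for quantifying those distortions on fully
synthetic data where the truth is known. It targets researchers working
with museum-specimen capture data from structured populations — the
motivating system is a two-subspecies pest moth sampled over ~120 years —
and provides:

* a **structured heterochronous coalescent simulator** (two demes,
  migration, constant or growth-then-plateau effective size
  ν = N<sub>e</sub> × generation time, in calendar years; coalescence at
  rate k(k−1)/(2ν) per year), with **GTR+Γ sequence simulation** along the
  genealogy and a **bycatch masker** that lays missingness down in
  contiguous runs until each sample hits its coverage target;
* **coverage filtering**: breadth measurement, nested ≥-threshold datasets
  (default grid 5%–65% in eleven steps), marker-window filters, OLS
  helpers;
* a from-scratch **DAPC** (Discriminant Analysis of Principal Components)
  for haploid alignments with missing data: minor-allele encoding, mean
  imputation, 30%-of-axes PC retention, a two-group discriminant with
  1-D Gaussian membership probabilities, admixture classification on the
  closed interval [0.01, 0.99], and site loadings;
* **phylodynamics**: the heterochronous coalescent likelihood, the classic
  skyline estimator, a fixed-genealogy **Bayesian skyline MCMC**
  (exponential(10,000) prior on the most recent ν, chained priors on older
  groups, adaptive log-normal proposals, 10% burnin, ESS diagnostics), and
  distance-based **dated tree estimation** from patchy alignments
  (pairwise-deletion JC distances, UPGMA, tip-date calibration);
* **tree statistics**: the largest labelled-only monophyletic clade as a
  proportion of labelled tips, evaluated over posterior-like tree sets;
* a **pipeline** (`run_experiment()`) chaining simulate → mask → threshold
  → per-threshold DAPC / tree / skyline / monophyly → cross-threshold
  summaries, byte-identical under a fixed seed.

## Worked example

Simulate a 28-sample two-deme dataset, mask it to 10% coverage breadth,
and compare inference against the truth:

```r
library(bycatchsim)

meta <- synthesize_meta(n_conferta = 20, n_armigera = 8,
                        sampling_window = c(1960, 2020), seed = 1)
dem  <- demography_config(nu_conferta = 2000, nu_armigera = 2000,
                          migration_rate = 0, sampling_window = c(1960, 2020))
tree <- simulate_genealogy(meta, dem, seed = 2)
tree
#> dated_tree: 28 tips, dates 1960.8-2019.5, root height 10843.0 years

aln    <- simulate_sequences(tree, gtr_params(clock_rate = 2e-5, gamma_shape = 1),
                             length = 4000, seed = 3)
masked <- apply_bycatch_mask(aln, mask_config(target_coverage = 0.10,
                                              mean_block_length = 300, seed = 4))
masked
#> haplo_alignment: 28 samples x 4000 sites (89.5% missing)

labs <- meta$prior_cluster[match(rownames(aln), meta$id)]
enc  <- encode_alignment(masked)
fit  <- dapc_fit(pca_reduce(enc, 0.30), labs, enc)
mean(fit$admixed)
#> [1] 0

est <- estimate_tree(masked, meta, clock_rate = 2e-5, min_overlap = 0)
round(root_height(est))
#> [1] 31939
largest_monophyletic_proportion(est, meta$id[meta$prior_cluster == "armigera"])
#> [1] 0.25
```

The numbers tell the missing-data story in miniature. At 10% coverage the
estimated root is **31,939 years** against a true root height of 10,843 —
low-coverage samples share few called sites, their pairwise distances are
noisy and saturated, and the dated tree comes out far too old, mirroring
the spuriously old demographic trajectories seen in low-coverage bycatch
analyses. Monophyly support collapses the same way: the armigera deme is
truly monophyletic (proportion 1.0 on the true tree), but only a clade of
2 of its 8 samples survives in the tree estimated from 10% coverage
(proportion 0.25). The DAPC still assigns every sample confidently here
(admixed proportion 0); the admixture inflation emerges as a *trend* over
replicate simulations and coverage levels, which is what the test suite
and pipeline measure.

`run_experiment(experiment_config(...), "out/")` runs the same comparison
across the full eleven-threshold grid and writes per-threshold membership
tables, trees, skyline posteriors, monophyly distributions and
cross-threshold summaries, deterministically for a given seed.

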