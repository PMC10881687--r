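test_that("coalescent log-likelihood matches closed forms", {
  # two contemporaneous tips, constant nu, coalescence at depth t
  t_dep <- 7; nu <- 100
  phy <- ape::read.tree(text = "(a:7,b:7);")
  tr <- dated_tree(phy, c(a = 2000, b = 2000))
  expect_equal(coalescent_loglik(tr, skyline_trajectory(nu)),
               -log(nu) - t_dep / nu, tolerance = 1e-12)
  # scaling times and nu by c shifts logL by -(#coalescences) log c
  cc <- 3.7
  phy_s <- phy; phy_s$edge.length <- phy$edge.length * cc
  tr_s <- dated_tree(phy_s, c(a = 2000, b = 2000))
  expect_equal(coalescent_loglik(tr_s, skyline_trajectory(nu * cc)),
               coalescent_loglik(tr, skyline_trajectory(nu)) - log(cc),
               tolerance = 1e-10)
  # constant-nu MLE for the two-tip case is nu-hat = t
  prof <- function(v) coalescent_loglik(tr, skyline_trajectory(v))
  opt <- stats::optimize(prof, c(0.01, 1000), maximum = TRUE)
  expect_equal(opt$maximum, t_dep, tolerance = 1e-3)
})

test_that("log-likelihood agrees with brute-force grid integration", {
  set.seed(5)
  for (s in 1:5) {
    tr <- random_dated_tree(10, seed = 40 + s)
    h <- root_height(tr)
    traj <- skyline_trajectory(
      nu = c(50, 200, 120),
      breaks = 2000 - c(0.3, 0.7) * h)
    expect_equal(coalescent_loglik(tr, traj),
                 oracle_coalescent_loglik(tr, traj),
                 tolerance = 1e-6)
  }
})

test_that("classic skyline reproduces hand-computed epoch estimates", {
  # isochronous 3 tips: k=3 for 2 years then k=2 for 3 years -> (6, 3)
  phy <- ape::read.tree(text = "((a:2,b:2):3,c:5);")
  tr <- dated_tree(phy, c(a = 2000, b = 2000, c = 2000))
  cs <- classic_skyline(tr)
  expect_equal(cs$nu, c(6, 3), tolerance = 1e-9)
  # two tips at depth t: single epoch nu-hat = t
  phy2 <- ape::read.tree(text = "(a:11,b:11);")
  tr2 <- dated_tree(phy2, c(a = 2000, b = 2000))
  expect_equal(classic_skyline(tr2)$nu, 11, tolerance = 1e-9)
})

test_that("classic skyline recovers constant nu in time-weighted average", {
  dem <- demography_config(1000, 1000, 0, sampling_window = c(1990, 2020))
  meta <- iso_meta(20)
  hm <- vapply(1:200, function(r) {
    tr <- simulate_genealogy(meta, dem, seed = 900 + r)
    cs <- classic_skyline(tr)
    root_t <- max(tr$tip_dates) - root_height(tr)
    dur <- c(max(tr$tip_dates), cs$breaks) - c(cs$breaks, root_t)
    sum(dur) / sum(dur / cs$nu)
  }, numeric(1))
  expect_equal(median(hm), 1000, tolerance = 0.15)
})

test_that("skyline MCMC applies the 10% burnin rule to the trace", {
  tr <- random_dated_tree(6, seed = 3)
  fit <- suppressWarnings(
    skyline_mcmc(tr, n_groups = 1, chain_length = 10000, sample_every = 10,
                 burnin_frac = 0.10, seed = 2))
  expect_equal(nrow(fit$trace), 900)
  expect_error(skyline_mcmc(tr, chain_length = 0),
               class = "bycatchsim_input_error")
  expect_error(skyline_mcmc(tr, n_groups = 50, chain_length = 1e4,
                            sample_every = 10),
               class = "bycatchsim_input_error")
})

test_that("posterior mode is consistent with the analytic constant-nu MLE", {
  dem <- demography_config(800, 800, 0, sampling_window = c(1990, 2020))
  tr <- simulate_genealogy(iso_meta(20), dem, seed = 77)
  gs <- bycatchsim:::skyline_groups(tr, 1L)
  mle <- gs$S / gs$C
  fit <- suppressWarnings(
    skyline_mcmc(tr, n_groups = 1, chain_length = 4e4, sample_every = 10,
                 seed = 5))
  expect_equal(unname(fit$trajectory$nu), unname(mle), tolerance = 0.25)
  expect_true(fit$acceptance > 0.1 && fit$acceptance < 0.6)
})

test_that("the ESS estimator behaves on iid and constant traces", {
  set.seed(8)
  x <- rnorm(1000)
  expect_gt(ess(x), 600)
  expect_lte(ess(x), 1400)
  expect_equal(ess(rep(2.5, 100)), 1)
  expect_error(ess(1:5), class = "bycatchsim_input_error")
})

test_that("tree estimation collapses identical sequences to zero depths", {
  m <- matrix("A", 5, 300, dimnames = list(paste0("s", 1:5), NULL))
  m[, 1:10] <- "C"
  aln <- haplo_alignment(m)
  meta <- iso_meta(5)
  tr <- estimate_tree(aln, meta, clock_rate = 1e-5)
  expect_equal(root_height(tr), 0, tolerance = 1e-9)
})

test_that("the deepest split separates well-diverged demes", {
  d <- make_two_deme_data(8, nu = 3000, migration = 0, clock = 2e-5,
                          L = 5000, seed = 51)
  est <- estimate_tree(d$aln, d$meta, clock_rate = 2e-5)
  for (dm in c("conferta", "armigera")) {
    expect_equal(
      largest_monophyletic_proportion(est, d$meta$id[d$meta$deme == dm]), 1)
  }
})

test_that("low coverage inflates the spread of pairwise distances", {
  d <- make_two_deme_data(8, nu = 3000, migration = 0, clock = 1e-5,
                          L = 15390, seed = 52)
  D_full <- jc_pairwise_distances(d$aln, min_overlap = 0)
  spread <- function(cv, seed) {
    m <- apply_bycatch_mask(d$aln, mask_config(cv, 300, seed = seed))
    D <- jc_pairwise_distances(m, min_overlap = 0)
    ut <- upper.tri(D)
    stats::var(D[ut] - D_full[ut])
  }
  expect_gt(spread(0.05, 7), spread(0.65, 8))
})

test_that("pairs below the overlap floor raise an error naming them", {
  m <- rbind(c("A", "C", "G", "N", "N", "N"),
             c("N", "N", "N", "A", "C", "G"),
             rep("A", 6))
  rownames(m) <- c("left", "right", "full")
  aln <- haplo_alignment(m)
  meta <- sample_meta(rownames(m), rep(2000, 3), rep("conferta", 3))
  expect_error(estimate_tree(aln, meta, 1e-5, min_overlap = 2),
               regexp = "left.*right")
})
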