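test_that("simulated genealogies place every tip at its collection date", {
  meta <- synthesize_meta(6, 6, c(1900, 2020), seed = 3)
  dem <- demography_config(2000, 1500, migration_rate = 5e-4,
                           sampling_window = c(1900, 2020))
  tr <- simulate_genealogy(meta, dem, seed = 7)
  nt <- node_times(tr)
  tips <- seq_len(ape::Ntip(tr$phy))
  expect_equal(unname(nt[tips]),
               unname(stats::setNames(meta$date, meta$id)[tr$phy$tip.label]),
               tolerance = 1e-8)
  # parents strictly older than children
  for (e in seq_len(nrow(tr$phy$edge))) {
    expect_lte(nt[tr$phy$edge[e, 1]], nt[tr$phy$edge[e, 2]] + 1e-9)
  }
})

test_that("first-coalescence times follow the k(k-1)/(2nu) rate", {
  # invariant: k contemporaneous lineages, constant nu -> mean waiting time
  # to the first coalescence is 2nu/(k(k-1))
  nu <- 1000
  dem <- demography_config(nu, nu, 0, sampling_window = c(1990, 2020))
  set.seed(42)
  for (k in c(4L, 8L)) {
    meta <- iso_meta(k)
    first <- replicate(600, {
      tr <- simulate_genealogy(meta, dem, seed = sample.int(1e8, 1))
      nt <- node_times(tr)
      2000 - max(nt[(k + 1):(2 * k - 1)])
    })
    expect_equal(mean(first), 2 * nu / (k * (k - 1)), tolerance = 0.12)
  }
})

test_that("growth-then-plateau demography accelerates deep coalescence", {
  # nu shrinks exponentially into the past before the plateau year, so
  # TMRCAs are younger than under a constant nu of the same plateau value
  meta <- iso_meta(10, date = 2020)
  win <- c(1900, 2020)
  const <- demography_config(5000, 5000, 0, sampling_window = win)
  grow <- demography_config(5000, 5000, 0,
                            growth = list(rate = 0.05, plateau_year = 1900),
                            sampling_window = win)
  set.seed(1)
  h_const <- replicate(200, root_height(
    simulate_genealogy(meta, const, seed = sample.int(1e8, 1))))
  h_grow <- replicate(200, root_height(
    simulate_genealogy(meta, grow, seed = sample.int(1e8, 1))))
  expect_lt(median(h_grow), median(h_const))
})

test_that("zero-migration two-deme genealogies are reciprocally monophyletic", {
  dem <- demography_config(2000, 2000, 0, sampling_window = c(1990, 2020))
  for (s in 1:20) {
    meta <- synthesize_meta(5, 5, c(1990, 2020), seed = s)
    tr <- simulate_genealogy(meta, dem, seed = 100 + s)
    for (d in c("conferta", "armigera")) {
      expect_equal(
        largest_monophyletic_proportion(tr, meta$id[meta$deme == d]), 1)
    }
  }
})

test_that("sequence simulation degenerates to identical sequences", {
  tr <- random_dated_tree(5, seed = 2)
  aln0 <- simulate_sequences(tr, gtr_params(clock_rate = 0), 200, seed = 4)
  m <- unclass(aln0)
  expect_true(all(m == rep(m[1, ], each = nrow(m))))
  # zero branch lengths likewise
  phy <- tr$phy
  phy$edge.length[] <- 0
  tr0 <- dated_tree(phy, stats::setNames(rep(2000, 5), phy$tip.label))
  alnz <- simulate_sequences(tr0, gtr_params(clock_rate = 1e-3), 200, seed = 5)
  mz <- unclass(alnz)
  expect_true(all(mz == rep(mz[1, ], each = nrow(mz))))
})

test_that("tip base frequencies reach stationarity on long paths", {
  pi <- c(0.35, 0.15, 0.10, 0.40)
  gp <- gtr_params(exchangeabilities = c(1, 4, 1, 1, 4, 1),
                   base_freqs = pi, gamma_shape = 1, clock_rate = 1e-3)
  phy <- ape::read.tree(text = "(a:10000,b:10000);")
  tr <- dated_tree(phy, c(a = 2000, b = 2000))
  aln <- simulate_sequences(tr, gp, 50000, seed = 6)
  for (i in 1:2) {
    freq <- table(factor(unclass(aln)[i, ], levels = c("A", "C", "G", "T")))
    expect_equal(as.numeric(freq / 50000), pi, tolerance = 0.08)
    expect_true(max(abs(freq / 50000 - pi)) < 0.01)
  }
})

test_that("discrete gamma rate multipliers are equal-probability with mean 1", {
  for (shape in c(0.3, 1, 5)) {
    r <- discrete_gamma_rates(shape, 4)
    expect_length(r, 4)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
  }
  expect_equal(discrete_gamma_rates(7, 1), 1)
})

test_that("bycatch masking hits its coverage targets and preserves bases", {
  d <- make_two_deme_data(10, L = 2000, seed = 11)
  # identity and total masking
  expect_identical(unclass(apply_bycatch_mask(d$aln, mask_config(1, 300, 1))),
                   unclass(d$aln))
  all_n <- apply_bycatch_mask(d$aln, mask_config(0, 300, 1))
  expect_true(all(unclass(all_n) == "N"))
  # realized coverage within +/-0.02 of target, unmasked bases bit-exact
  masked <- apply_bycatch_mask(d$aln, mask_config(0.40, 150, seed = 9))
  cov <- coverage_proportion(masked)$per_sample
  expect_true(all(abs(cov - 0.40) <= 0.02 + 1e-9))
  keep <- unclass(masked) != "N"
  expect_identical(unclass(masked)[keep], unclass(d$aln)[keep])
})

test_that("per-sample coverage tolerance holds at mitogenome scale", {
  base <- haplo_alignment(matrix("A", 40, 15390,
                                 dimnames = list(sprintf("s%02d", 1:40), NULL)))
  masked <- apply_bycatch_mask(base, mask_config(0.40, 300, seed = 2))
  cov <- coverage_proportion(masked)$per_sample
  expect_true(all(cov >= 0.38 - 1e-9 & cov <= 0.42 + 1e-9))
})

test_that("masking rejects invalid coverage targets", {
  d <- make_two_deme_data(4, L = 200, seed = 12)
  expect_error(apply_bycatch_mask(d$aln, mask_config(function(n) rep(1.5, n),
                                                     300, 1)),
               class = "bycatchsim_input_error")
  expect_error(mask_config(-0.1), class = "bycatchsim_input_error")
})

test_that("dates-only tree sets match the exponential prior mean", {
  meta <- iso_meta(2)
  ts <- simulate_dates_only_trees(meta, prior_mean = 10000, n_trees = 1000,
                                  seed = 3)
  depths <- vapply(ts, root_height, numeric(1))
  expect_equal(mean(depths), 10000, tolerance = 0.05)
  # heterochronous tips keep their dates in every tree
  meta2 <- sample_meta(c("a", "b", "c"), c(1950, 1980, 2020),
                       rep("conferta", 3))
  ts2 <- simulate_dates_only_trees(meta2, 5000, n_trees = 20, seed = 4)
  for (tr in ts2) {
    nt <- node_times(tr)
    expect_equal(unname(nt[seq_len(3)]),
                 unname(stats::setNames(meta2$date, meta2$id)[tr$phy$tip.label]),
                 tolerance = 1e-8)
  }
  expect_error(simulate_dates_only_trees(meta, 10000, n_trees = 0),
               class = "bycatchsim_input_error")
})
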