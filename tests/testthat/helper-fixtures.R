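# Fixtures and independent oracles shared by the test files.  Everything is
# generated in code; nothing is read from disk.

# small alignment from explicit strings (rows = samples)
aln_from_strings <- function(strs, ids = paste0("s", seq_along(strs))) {
  m <- do.call(rbind, strsplit(strs, ""))
  rownames(m) <- ids
  haplo_alignment(m)
}

# two-deme dataset: genealogy + full-coverage alignment + labels
make_two_deme_data <- function(n_per_deme = 20, nu = 2000, migration = 0,
                               clock = 2e-5, L = 4000, seed = 1,
                               window = c(1990, 2020)) {
  meta <- synthesize_meta(n_per_deme, n_per_deme, window, seed = seed)
  dem <- demography_config(nu, nu, migration, sampling_window = window)
  tree <- simulate_genealogy(meta, dem, seed = seed + 1000)
  aln <- simulate_sequences(tree, gtr_params(clock_rate = clock,
                                             gamma_shape = 1),
                            L, seed = seed + 2000)
  labs <- meta$prior_cluster[match(rownames(aln), meta$id)]
  list(meta = meta, tree = tree, aln = aln, labs = labs)
}

# contemporaneous single-deme metadata
iso_meta <- function(n, date = 2000) {
  sample_meta(paste0("s", seq_len(n)), rep(date, n), rep("conferta", n))
}

# --- monophyly oracle: enumerate every clade tip set explicitly ------------
# (the implementation uses a single post-order pass; this oracle extracts
# each internal node's descendant tip set via ape and scans them all)
oracle_monophyly <- function(phy, labels) {
  tipsets <- c(
    as.list(phy$tip.label),                               # single tips
    lapply(ape::prop.part(phy), function(ix) phy$tip.label[ix])
  )
  sizes <- vapply(tipsets, function(ts) {
    if (all(ts %in% labels)) length(ts) else 0L
  }, integer(1))
  max(sizes) / length(labels)
}

# --- closed-form normal-equations regression oracle ------------------------
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  sst <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2],
       r_squared = 1 - sum(resid^2) / sst)
}

# --- generalized eigenproblem oracle for the two-group discriminant --------
# between/within scatter of the PC scores; leading eigenvector of W^-1 B
oracle_discriminant_axis <- function(scores, labs) {
  lev <- sort(unique(labs))
  g1 <- labs == lev[1]
  m1 <- colMeans(scores[g1, , drop = FALSE])
  m2 <- colMeans(scores[!g1, , drop = FALSE])
  mg <- colMeans(scores)
  n1 <- sum(g1); n2 <- sum(!g1)
  B <- n1 * tcrossprod(m1 - mg) + n2 * tcrossprod(m2 - mg)
  W <- crossprod(sweep(scores[g1, , drop = FALSE], 2, m1)) +
    crossprod(sweep(scores[!g1, , drop = FALSE], 2, m2))
  ev <- eigen(solve(W, B))
  ax <- Re(ev$vectors[, which.max(Re(ev$values))])
  ax / sqrt(sum(ax^2))
}

# --- brute-force coalescent likelihood by fine-grid integration ------------
oracle_coalescent_loglik <- function(tree, traj, n_grid = 20000) {
  iv <- bycatchsim:::tree_intervals(tree)
  ll <- 0
  for (r in seq_len(nrow(iv$intervals))) {
    k <- iv$intervals$k[r]
    if (k < 2) next
    hi <- iv$intervals$t_young[r]; lo <- iv$intervals$t_old[r]
    ts <- seq(lo, hi, length.out = n_grid)
    mid <- (ts[-1] + ts[-n_grid]) / 2
    nu <- vapply(mid, function(t) skyline_nu_at(traj, t), numeric(1))
    ll <- ll - sum(k * (k - 1) / (2 * nu) * diff(ts))
  }
  ll - sum(log(vapply(iv$coal_times,
                      function(tc) skyline_nu_at(traj, tc), numeric(1))))
}

# smoke-scale experiment configuration (24 samples, 2 kb, 2 thresholds)
tiny_cfg <- function(seed = 42) {
  experiment_config(
    n_conferta = 18, n_armigera = 6, seq_length = 2000,
    demography = demography_config(2000, 2000, 1e-4,
                                   sampling_window = c(1960, 2020)),
    gtr = gtr_params(clock_rate = 2e-5, gamma_shape = 1),
    thresholds = c(0.05, 0.5),
    chain_length = 5000, sample_every = 10,
    n_dates_only_trees = 30, monophyly_n_subsample = 50,
    min_overlap = 0, seed = seed)
}

# random rooted non-ultrametric tree as a dated_tree (tips contemporaneous
# trees are not needed; rcoal gives ultrametric, rtree arbitrary heights)
random_dated_tree <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
  phy$edge.length <- phy$edge.length * 100
  dated_tree(phy, stats::setNames(rep(2000, n), phy$tip.label))
}
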