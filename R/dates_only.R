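#' Simulate a dates-only posterior stand-in tree set
#'
#' Emulates an analysis with a constant phylogenetic likelihood, where only
#' the sampling dates and the priors shape the posterior: for each tree a
#' constant \eqn{\nu} is drawn from an exponential prior with the given
#' mean, and a single-deme heterochronous coalescent genealogy is simulated
#' on the observed dates. The collection approximates the posterior tree
#' distribution such an analysis would produce.
#'
#' @param meta a [sample_meta()] table (demes are ignored; one panmictic
#'   pool).
#' @param prior_mean mean of the exponential prior on \eqn{\nu}
#'   (default 10000 years).
#' @param n_trees number of trees to draw (>= 1).
#' @param seed integer seed.
#' @return list of [dated_tree()] objects of class `tree_set`.
#' @export
simulate_dates_only_trees <- function(meta, prior_mean = 10000,
                                      n_trees = 1000L, seed = 1L) {
  if (n_trees < 1L) input_error("n_trees must be >= 1")
  if (prior_mean <= 0) input_error("prior_mean must be positive")
  set.seed(seed)
  meta1 <- meta
  meta1$deme <- "conferta"
  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    nu <- stats::rexp(1L, rate = 1 / prior_mean)
    dem <- demography_config(nu_conferta = nu, nu_armigera = nu,
                             migration_rate = 0,
                             sampling_window = range(meta$date))
    trees[[i]] <- simulate_genealogy(meta1, dem,
                                     seed = sample.int(2147483646L, 1L))
  }
  structure(trees, class = "tree_set")
}
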