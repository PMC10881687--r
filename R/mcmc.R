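#' Effective sample size of an MCMC trace
#'
#' Initial-positive-sequence estimator: `ESS = n / (1 + 2 * sum(rho_k))`,
#' with the autocorrelation sum truncated at the first even-lag pair
#' `rho_{2m+1} + rho_{2m+2}` that is non-positive. A constant trace has
#' ESS 1 by convention.
#'
#' @param x numeric trace, length >= 10.
#' @return estimated effective sample size (capped at `length(x)`).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10L) input_error("trace must have length >= 10")
  if (stats::sd(x) == 0) return(1)
  rho <- drop(stats::acf(x, lag.max = n - 1L, plot = FALSE,
                         demean = TRUE)$acf)[-1L]
  s <- 0
  m <- 1L
  while (m + 1L <= length(rho)) {
    pair <- rho[m] + rho[m + 1L]
    if (pair <= 0) break
    s <- s + pair
    m <- m + 2L
  }
  min(n, n / (1 + 2 * s))
}

# internal: grouped sufficient statistics of a dated tree for a skyline
# with contiguous coalescent-event groups.  Interval r contributes
# k(k-1)/2 * dt to the group of the next coalescent event looking backward.
skyline_groups <- function(tree, n_groups) {
  iv <- tree_intervals(tree)
  coal <- iv$coal_times                       # decreasing (recent -> old)
  E <- length(coal)
  if (n_groups > E) input_error("n_groups exceeds the number of coalescent events")
  grp_of_event <- if (n_groups == 1L) rep(1L, E) else {
    as.integer(cut(seq_len(E), n_groups, labels = FALSE))
  }
  S <- numeric(n_groups); C <- tabulate(grp_of_event, n_groups)
  ci <- 1L
  for (r in seq_len(nrow(iv$intervals))) {
    k <- iv$intervals$k[r]
    hi <- iv$intervals$t_young[r]; lo <- iv$intervals$t_old[r]
    g <- grp_of_event[min(ci, E)]
    if (k >= 2L) S[g] <- S[g] + k * (k - 1) / 2 * (hi - lo)
    while (ci <= E && lo <= coal[ci] + 1e-12) ci <- ci + 1L
  }
  # calendar boundary between group g and g+1: oldest event of group g
  breaks <- vapply(seq_len(n_groups - 1L),
                   function(g) min(coal[grp_of_event == g]), numeric(1))
  list(S = S, C = C, breaks = breaks, present = iv$present,
       root_time = min(coal))
}

#' Fixed-genealogy Bayesian skyline MCMC
#'
#' Metropolis-Hastings sampler for a piecewise-constant \eqn{\nu} on a fixed
#' dated genealogy. Coalescent intervals are partitioned into `n_groups`
#' contiguous groups with event counts as equal as possible. The most
#' recent group's \eqn{\nu} carries an exponential prior with mean
#' `prior_mean`; each older group's \eqn{\nu} carries an exponential prior
#' whose mean is its younger neighbour's current value (skyline-style
#' chained smoothing). Proposals are multiplicative log-normal with step
#' sizes adapted during burnin toward 20-40% acceptance. `likelihood_off`
#' gives a prior-only (dates-uninformed) run.
#'
#' The post-burnin ESS of every group is compared against 200; values below
#' raise a warning, not an error.
#'
#' @param tree a [dated_tree()].
#' @param n_groups number of skyline groups; default
#'   `min(10, floor(events/2))`, at least 1.
#' @param prior_mean exponential prior mean on the most recent \eqn{\nu}
#'   (default 10000 years).
#' @param chain_length total MCMC steps (default 1e5; the full-scale
#'   setting 2e8 with sampling every 1e5 is available by argument).
#' @param sample_every thinning interval (default 50).
#' @param burnin_frac fraction of recorded samples discarded (default
#'   0.10).
#' @param seed integer seed.
#' @param likelihood_off if `TRUE`, sample the prior only.
#' @return list of class `skyline_mcmc`: `trace` (post-burnin data.frame
#'   `step`, `nu_1..nu_G`), `ess` per group, `acceptance`, `trajectory`
#'   (posterior median [skyline_trajectory()] with 95% credible bounds),
#'   `n_groups`.
#' @export
skyline_mcmc <- function(tree, n_groups = NULL, prior_mean = 10000,
                         chain_length = 1e5, sample_every = 50,
                         burnin_frac = 0.10, seed = 1L,
                         likelihood_off = FALSE) {
  if (chain_length < 1 || sample_every < 1) {
    input_error("chain settings must be positive")
  }
  E <- length(tree_intervals(tree)$coal_times)
  if (is.null(n_groups)) n_groups <- max(1L, min(10L, E %/% 2L))
  gs <- skyline_groups(tree, n_groups)
  n_kept <- floor(chain_length / sample_every)
  if ((1 - burnin_frac) * n_kept < 100) {
    input_error("need >= 100 post-burnin samples; lengthen the chain")
  }
  set.seed(seed)

  G <- n_groups
  log_target <- function(nu) {
    lp <- stats::dexp(nu[1L], 1 / prior_mean, log = TRUE)
    if (G > 1L) {
      lp <- lp + sum(stats::dexp(nu[-1L], 1 / nu[-G], log = TRUE))
    }
    if (!likelihood_off) {
      lp <- lp + sum(-gs$C * log(nu) - gs$S / nu)
    }
    lp
  }

  nu <- rep(prior_mean, G)
  if (!likelihood_off) nu <- pmax(gs$S / pmax(gs$C, 1L), 1e-8)  # crude MLE start
  lt <- log_target(nu)
  sigma <- rep(1, G)
  n_prop <- n_acc <- rep(0L, G)
  adapt_until <- burnin_frac * chain_length

  trace <- matrix(NA_real_, n_kept, G)
  steps <- integer(n_kept)
  kept <- 0L
  for (it in seq_len(chain_length)) {
    g <- if (G == 1L) 1L else sample.int(G, 1L)
    prop <- nu
    prop[g] <- nu[g] * exp(sigma[g] * stats::rnorm(1L))
    lt_prop <- log_target(prop)
    log_alpha <- lt_prop - lt + log(prop[g] / nu[g])   # Hastings term
    n_prop[g] <- n_prop[g] + 1L
    acc <- log(stats::runif(1L)) < log_alpha
    if (acc) { nu <- prop; lt <- lt_prop; n_acc[g] <- n_acc[g] + 1L }
    if (it <= adapt_until) {
      sigma[g] <- sigma[g] * exp((as.numeric(acc) - 0.3) / sqrt(n_prop[g]))
    }
    if (it %% sample_every == 0) {
      kept <- kept + 1L
      trace[kept, ] <- nu
      steps[kept] <- it
    }
  }

  drop_n <- floor(burnin_frac * kept)
  keep_idx <- (drop_n + 1L):kept
  post <- trace[keep_idx, , drop = FALSE]
  ess_vals <- apply(post, 2L, ess)
  if (any(ess_vals < 200)) {
    warning(sprintf("post-burnin ESS below 200 for %d of %d groups (min %.0f)",
                    sum(ess_vals < 200), G, min(ess_vals)))
  }
  med <- apply(post, 2L, stats::median)
  lo <- apply(post, 2L, stats::quantile, probs = 0.025)
  hi <- apply(post, 2L, stats::quantile, probs = 0.975)
  brk <- gs$breaks
  if (length(brk) > 1L) {            # tied event times: keep strict order
    for (i in 2:length(brk)) {
      if (brk[i] >= brk[i - 1L]) brk[i] <- brk[i - 1L] - 1e-9
    }
  }
  traj <- skyline_trajectory(med, breaks = brk, lower = lo, upper = hi)

  tr <- data.frame(step = steps[keep_idx], post)
  names(tr) <- c("step", paste0("nu_", seq_len(G)))
  structure(list(
    trace = tr, ess = ess_vals,
    acceptance = ifelse(n_prop > 0, n_acc / n_prop, NA_real_),
    trajectory = traj, n_groups = G,
    group_stats = gs
  ), class = "skyline_mcmc")
}

#' Write skyline posterior and trace outputs
#'
#' @param fit a [skyline_mcmc()] result.
#' @param skyline_path CSV path for epoch summaries (epoch_start_year,
#'   epoch_end_year, nu_median, nu_low, nu_high); start is the younger
#'   bound.
#' @param trace_path optional CSV path for the post-burnin trace.
#' @export
write_skyline_csv <- function(fit, skyline_path, trace_path = NULL) {
  traj <- fit$trajectory
  gs <- fit$group_stats
  starts <- c(gs$present, traj$breaks)
  ends <- c(traj$breaks, gs$root_time)
  utils::write.csv(data.frame(
    epoch_start_year = starts, epoch_end_year = ends,
    nu_median = traj$nu, nu_low = traj$lower, nu_high = traj$upper
  ), skyline_path, row.names = FALSE, quote = FALSE)
  if (!is.null(trace_path)) {
    utils::write.csv(fit$trace, trace_path, row.names = FALSE, quote = FALSE)
  }
  invisible(skyline_path)
}
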