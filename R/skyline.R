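#' Piecewise-constant effective-size trajectory
#'
#' A skyline trajectory holds \eqn{\nu = N_e \times} generation time (years)
#' as a step function of calendar time. Epoch 1 is the most recent and
#' extends toward the present/future; `breaks` are the epoch boundaries in
#' strictly decreasing calendar years, so epoch `i` covers times in
#' `(breaks[i], breaks[i-1]]` and the last epoch extends indefinitely into
#' the past.
#'
#' @param nu positive per-epoch values, most recent first.
#' @param breaks decreasing calendar years, length `length(nu) - 1`.
#' @param lower,upper optional per-epoch credible bounds.
#' @return object of class `skyline_trajectory`.
#' @export
skyline_trajectory <- function(nu, breaks = numeric(0),
                               lower = NULL, upper = NULL) {
  if (any(nu <= 0)) input_error("nu must be positive everywhere")
  if (length(breaks) != length(nu) - 1L) {
    input_error("need length(nu) - 1 epoch boundaries")
  }
  if (length(breaks) > 1L && any(diff(breaks) >= 0)) {
    input_error("breaks must strictly decrease toward the past")
  }
  structure(list(nu = nu, breaks = breaks, lower = lower, upper = upper),
            class = "skyline_trajectory")
}

# internal: epoch index at calendar time t (boundary belongs to older epoch)
skyline_epoch_at <- function(traj, t) {
  1L + sum(traj$breaks >= t)
}

#' @rdname skyline_trajectory
#' @param traj a `skyline_trajectory`.
#' @param t calendar time (decimal year).
#' @export
skyline_nu_at <- function(traj, t) {
  traj$nu[skyline_epoch_at(traj, t)]
}

# internal: inter-event interval table of a dated tree, walking backward
# from the most recent tip.  Returns intervals (t_young > t_old) with the
# lineage count k holding over each, plus the coalescent event times.
tree_intervals <- function(dt) {
  phy <- dt$phy
  ntip <- ape::Ntip(phy)
  nt <- node_times(dt)
  ev_time <- c(nt[seq_len(ntip)], nt[(ntip + 1L):length(nt)])
  ev_delta <- c(rep(1L, ntip), rep(-1L, phy$Nnode))
  times_u <- sort(unique(ev_time), decreasing = TRUE)
  k <- 0L
  t_young <- t_old <- numeric(0); kk <- integer(0)
  for (i in seq_along(times_u)) {
    tt <- times_u[i]
    if (i > 1L) {
      t_young <- c(t_young, times_u[i - 1L])
      t_old <- c(t_old, tt)
      kk <- c(kk, k)
    }
    k <- k + sum(ev_delta[ev_time == tt])
  }
  list(
    intervals = data.frame(t_young = t_young, t_old = t_old, k = kk),
    coal_times = sort(nt[(ntip + 1L):length(nt)], decreasing = TRUE),
    present = max(dt$tip_dates)
  )
}

#' Heterochronous coalescent log-likelihood of a dated tree
#'
#' Standard piecewise-constant coalescent density: over every inter-event
#' interval with k extant lineages the log-likelihood accumulates
#' \eqn{-k(k-1)\Delta t/(2\nu(t))} (split at trajectory boundaries), and
#' each coalescent event at time \eqn{t_c} contributes \eqn{-\log\nu(t_c)}.
#' Sampling events change k without a density term.
#'
#' @param tree a [dated_tree()].
#' @param traj a [skyline_trajectory()].
#' @return the log-likelihood (a real scalar).
#' @export
coalescent_loglik <- function(tree, traj) {
  if (any(traj$nu <= 0)) input_error("nu must be positive")
  iv <- tree_intervals(tree)
  ll <- 0
  for (r in seq_len(nrow(iv$intervals))) {
    k <- iv$intervals$k[r]
    if (k < 2L) next
    hi <- iv$intervals$t_young[r]; lo <- iv$intervals$t_old[r]
    cuts <- traj$breaks[traj$breaks < hi & traj$breaks > lo]
    pts <- c(hi, cuts, lo)
    for (s in seq_len(length(pts) - 1L)) {
      mid <- (pts[s] + pts[s + 1L]) / 2
      ll <- ll - k * (k - 1) / (2 * skyline_nu_at(traj, mid)) *
        (pts[s] - pts[s + 1L])
    }
  }
  ll - sum(log(vapply(iv$coal_times, function(tc) skyline_nu_at(traj, tc),
                      numeric(1))))
}

#' Classic skyline estimator
#'
#' Deterministic per-interval maximum-likelihood companion to the Bayesian
#' skyline: for each inter-coalescent interval,
#' \eqn{\hat\nu = \sum k(k-1)\Delta t / 2} accumulated over the sub-intervals
#' between successive coalescences — the heterochronous generalization of
#' the isochronous estimator, with sampling events merely changing k.
#'
#' @param tree a [dated_tree()].
#' @return a [skyline_trajectory()] with one epoch per coalescent event
#'   (most recent first); zero-length intervals yield \eqn{\hat\nu = 0},
#'   flagged via attribute `degenerate` (such epochs are floored at a tiny
#'   positive value to keep the trajectory valid).
#' @export
classic_skyline <- function(tree) {
  iv <- tree_intervals(tree)
  coal <- iv$coal_times                      # decreasing: recent -> old
  acc <- 0
  nu_hat <- numeric(0)
  ci <- 1L
  for (r in seq_len(nrow(iv$intervals))) {
    k <- iv$intervals$k[r]
    hi <- iv$intervals$t_young[r]; lo <- iv$intervals$t_old[r]
    acc <- acc + k * (k - 1) / 2 * (hi - lo)
    while (ci <= length(coal) && abs(lo - coal[ci]) < 1e-12) {
      nu_hat <- c(nu_hat, acc)
      acc <- 0
      ci <- ci + 1L
    }
  }
  while (ci <= length(coal)) {       # events at/"before" the first interval
    nu_hat <- c(nu_hat, acc)
    acc <- 0
    ci <- ci + 1L
  }
  degen <- nu_hat <= 0
  nu_hat[degen] <- .Machine$double.eps
  breaks <- coal[-length(coal)]
  if (length(breaks) > 1L) {         # tied event times: keep strict order
    for (i in 2:length(breaks)) {
      if (breaks[i] >= breaks[i - 1L]) breaks[i] <- breaks[i - 1L] - 1e-9
    }
  }
  out <- skyline_trajectory(nu_hat, breaks = breaks)
  attr(out, "degenerate") <- degen
  out
}
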