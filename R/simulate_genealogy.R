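#' Simulate a structured heterochronous coalescent genealogy
#'
#' Runs the two-deme structured coalescent backwards in time on the given
#' sampling dates. Within a deme holding k extant lineages, pairs coalesce
#' at rate \eqn{k(k-1)/(2\nu_{deme}(t))} per year; lineages switch demes at
#' `migration_rate` per lineage per year; tips enter the process at their
#' collection dates. Time-varying \eqn{\nu} is handled by time-rescaling
#' inversion of the cumulative coalescent intensity.
#'
#' With `migration_rate = 0` and both demes present, each deme first
#' coalesces to a single ancestral lineage; the two deme ancestors are then
#' joined through a pairwise coalescent in an ancestral pool whose constant
#' \eqn{\nu} is the mean of the two deme plateau values, so every genealogy
#' terminates and the demes come out reciprocally monophyletic.
#'
#' @param meta a [sample_meta()] table; `deme` must use labels `"conferta"`
#'   and/or `"armigera"`.
#' @param demography a [demography_config()].
#' @param seed integer seed.
#' @return a [dated_tree()] whose tips are `meta$id` at `meta$date`.
#' @export
simulate_genealogy <- function(meta, demography, seed = 1L) {
  if (nrow(meta) < 2L) input_error("need at least 2 samples")
  if (!all(meta$deme %in% c("conferta", "armigera"))) {
    input_error("deme labels must be 'conferta' or 'armigera'")
  }
  set.seed(seed)
  trajs <- list(
    conferta = deme_trajectory(demography$nu["conferta"],
                               demography$growth$conferta),
    armigera = deme_trajectory(demography$nu["armigera"],
                               demography$growth$armigera)
  )
  mig <- demography$migration_rate
  nu_anc <- mean(demography$nu)

  ord <- order(meta$date, decreasing = TRUE)
  pend_id <- meta$id[ord]
  pend_date <- meta$date[ord]
  pend_deme <- meta$deme[ord]

  # active lineage state: newick fragment, node time, deme label
  nwk <- character(0); ntime <- numeric(0); ndeme <- character(0)
  add_tips <- function(at) {
    take <- which(pend_date >= at - 1e-9)
    nwk <<- c(nwk, pend_id[take])
    ntime <<- c(ntime, pend_date[take])
    ndeme <<- c(ndeme, pend_deme[take])
    pend_id <<- pend_id[-take]
    pend_date <<- pend_date[-take]
    pend_deme <<- pend_deme[-take]
  }

  t <- pend_date[1L]
  add_tips(t)

  join <- function(i, j, at) {
    b1 <- ntime[i] - at; b2 <- ntime[j] - at
    new <- sprintf("(%s:%.12g,%s:%.12g)", nwk[i], b1, nwk[j], b2)
    keep <- setdiff(seq_along(nwk), c(i, j))
    nwk <<- c(nwk[keep], new)
    ntime <<- c(ntime[keep], at)
    ndeme <<- c(ndeme[keep], ndeme[i])
  }

  repeat {
    n_act <- length(nwk)
    if (n_act <= 1L && length(pend_id) == 0L) break
    next_samp <- if (length(pend_date)) pend_date[1L] else -Inf
    if (n_act <= 1L) { t <- next_samp; add_tips(t); next }

    k_c <- sum(ndeme == "conferta"); k_a <- sum(ndeme == "armigera")
    w_c <- traj_invert_waiting(trajs$conferta, t, k_c, stats::rexp(1))
    w_a <- traj_invert_waiting(trajs$armigera, t, k_a, stats::rexp(1))
    w_m <- if (mig > 0) stats::rexp(1) / (n_act * mig) else Inf
    w <- min(w_c, w_a, w_m)

    if (!is.finite(w)) {
      # migration 0, each deme down to one lineage: ancestral pool join
      w <- stats::rexp(1) * nu_anc
      if (t - w < next_samp) { t <- next_samp; add_tips(t); next }
      t <- t - w
      join(1L, 2L, t)
      next
    }
    if (t - w < next_samp) { t <- next_samp; add_tips(t); next }
    t <- t - w
    if (w == w_m) {
      i <- sample.int(n_act, 1L)
      ndeme[i] <- if (ndeme[i] == "conferta") "armigera" else "conferta"
    } else {
      d <- if (w == w_c) "conferta" else "armigera"
      idx <- which(ndeme == d)
      pick <- idx[sample.int(length(idx), 2L)]
      join(pick[1L], pick[2L], t)
    }
  }

  phy <- ape::read.tree(text = paste0(nwk, ";"))
  dated_tree(phy, stats::setNames(meta$date, meta$id))
}
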