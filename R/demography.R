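#' Demographic configuration for the two-deme coalescent
#'
#' Effective size is everywhere the compound \eqn{\nu = N_e \times} generation
#' time, in calendar years, so coalescence of k lineages within a deme occurs
#' at rate \eqn{k(k-1)/(2\nu)} per year and no separate generation time is
#' needed. Each deme's \eqn{\nu} is either constant or follows a
#' growth-then-plateau trajectory: exponential growth (forward in time) up to
#' a plateau year, constant at `nu` afterwards — the shape typical of an
#' expanding pest population that saturates.
#'
#' @param nu_conferta,nu_armigera present-day (plateau) \eqn{\nu} per deme,
#'   in years; must be positive.
#' @param migration_rate per-lineage per-year backward migration rate between
#'   the demes; non-negative.
#' @param growth `NULL` for constant size, or `list(rate =, plateau_year =)`
#'   applied to both demes (rate in 1/years, > 0 grows forward in time), or a
#'   named list `list(conferta =, armigera =)` of such lists (or `NULL`s).
#' @param sampling_window numeric length-2 `(earliest, latest)` decimal years.
#' @return an object of class `demography_config`.
#' @export
demography_config <- function(nu_conferta, nu_armigera,
                              migration_rate = 0,
                              growth = NULL,
                              sampling_window = c(1900, 2020)) {
  if (nu_conferta <= 0 || nu_armigera <= 0) input_error("nu must be > 0")
  if (migration_rate < 0) input_error("migration_rate must be >= 0")
  if (sampling_window[1] > sampling_window[2]) {
    input_error("sampling window earliest must not exceed latest")
  }
  per_deme <- function(g) {
    if (is.null(g)) return(list(conferta = NULL, armigera = NULL))
    if (!is.null(g$rate)) return(list(conferta = g, armigera = g))
    list(conferta = g$conferta, armigera = g$armigera)
  }
  g <- per_deme(growth)
  chk <- function(gi) {
    if (!is.null(gi) && (gi$rate <= 0 || is.null(gi$plateau_year))) {
      input_error("growth needs positive rate and a plateau_year")
    }
  }
  chk(g$conferta); chk(g$armigera)
  structure(list(
    nu = c(conferta = nu_conferta, armigera = nu_armigera),
    migration_rate = migration_rate,
    growth = g,
    sampling_window = as.numeric(sampling_window)
  ), class = "demography_config")
}

# internal: trajectory object for one deme
# nu(t) = nu0                                for t >= plateau_year
# nu(t) = nu0 * exp(-rate * (plateau_year-t)) for t <  plateau_year
deme_trajectory <- function(nu0, growth) {
  if (is.null(growth)) {
    list(type = "constant", nu0 = nu0)
  } else {
    list(type = "growth_plateau", nu0 = nu0,
         rate = growth$rate, plateau_year = growth$plateau_year)
  }
}

# internal: nu(t) at calendar time t
traj_nu_at <- function(traj, t) {
  if (traj$type == "constant" || t >= traj$plateau_year) return(traj$nu0)
  traj$nu0 * exp(-traj$rate * (traj$plateau_year - t))
}

# internal: time-rescaling inversion.  Given k lineages at calendar time
# t_cur and a unit-exponential deviate E, return the backward waiting time w
# solving  int_0^w k(k-1) / (2 nu(t_cur - s)) ds = E.  Into the past the
# growth-then-plateau nu shrinks, so the cumulative intensity diverges and w
# is always finite.
traj_invert_waiting <- function(traj, t_cur, k, E) {
  if (k < 2L) return(Inf)
  cc <- k * (k - 1) / 2
  if (traj$type == "constant") return(E * traj$nu0 / cc)
  seg <- max(0, t_cur - traj$plateau_year)     # constant piece, if any
  I_const <- cc * seg / traj$nu0
  if (E <= I_const) return(E * traj$nu0 / cc)
  # exponential piece; nu at its start (calendar min(t_cur, plateau_year))
  Erem <- E - I_const
  nu_start <- traj_nu_at(traj, min(t_cur, traj$plateau_year))
  u <- log1p(Erem * nu_start * traj$rate / cc) / traj$rate
  seg + u
}
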