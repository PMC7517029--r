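#' SIR model parameters
#'
#' Classical SIR model without demography,
#' \deqn{\dot S = -\beta S I,\quad \dot I = (\beta S - \gamma) I,\quad
#'       \dot R = \gamma I,}
#' with transmission rate `beta` and recovery rate `gamma` (both per year in
#' this package's conventions).  The threshold susceptible level is
#' \eqn{\gamma/\beta}: the infection initially grows iff
#' \eqn{S_0 > \gamma/\beta}.
#'
#' @param beta Transmission rate, `> 0` (1/year per unit population).
#' @param gamma Recovery rate, `> 0` (1/year).
#' @return A list of class `sir_params` with `beta`, `gamma` and the
#'   reproduction ratio `R_star = beta/gamma`.
#' @export
sir_params <- function(beta, gamma) {
  if (beta <= 0 || gamma <= 0) abort("`beta` and `gamma` must be positive.")
  structure(list(beta = beta, gamma = gamma, R_star = beta / gamma),
            class = "sir_params")
}

#' Controlled SIS model parameters
#'
#' SIS model with vaccination and treatment feedback controls
#' \eqn{V(t) = k_V S(t)} and \eqn{T(t) = k_T I(t)}:
#' \deqn{\dot S = \gamma I - \beta S I - k_V S,\quad
#'       \dot I = (\beta S - \gamma - k_T) I,\quad
#'       \dot R = k_V S + k_T I.}
#' The recovered compartment is kept explicit so that total-population
#' conservation \eqn{S+I+R = N_0} is checkable.
#'
#' @inheritParams sir_params
#' @param kV Vaccination feedback gain, `>= 0` (1/year).
#' @param kT Treatment feedback gain, `>= 0` (1/year).
#' @return A list of class `sis_params`.
#' @export
sis_params <- function(beta, gamma, kV = 0, kT = 0) {
  if (beta <= 0 || gamma <= 0) abort("`beta` and `gamma` must be positive.")
  if (kV < 0 || kT < 0) abort("`kV` and `kT` must be nonnegative.")
  structure(list(beta = beta, gamma = gamma, kV = kV, kT = kT),
            class = "sis_params")
}

#' SIR right-hand side
#'
#' @param params A [sir_params()].
#' @param state Named or positional numeric vector `(S, I, R)`, nonnegative.
#' @return Derivative vector `(dS, dI, dR)`; the components sum to zero, so
#'   the total population is conserved.
#' @export
sir_rhs <- function(params, state) {
  S <- state[[1L]]; I <- state[[2L]]
  with(params, c(S = -beta * S * I,
                 I = (beta * S - gamma) * I,
                 R = gamma * I))
}

#' Controlled-SIS right-hand side
#'
#' @param params A [sis_params()].
#' @inheritParams sir_rhs
#' @return Derivative vector `(dS, dI, dR)` summing to zero.
#' @export
sis_rhs <- function(params, state) {
  S <- state[[1L]]; I <- state[[2L]]
  with(params, c(S = gamma * I - beta * S * I - kV * S,
                 I = (beta * S - gamma - kT) * I,
                 R = kV * S + kT * I))
}

#' Equilibria of the controlled SIS model
#'
#' With a positive vaccination gain the only equilibrium is total removal,
#' `(0, 0, N0)`.  Without vaccination (`kV = 0`) there is additionally the
#' disease-free state with residual susceptibles at the threshold level
#' \eqn{S^* = (\gamma + k_T)/\beta}, reachable when that level does not
#' exceed the population.
#'
#' @param params A [sis_params()].
#' @param N0 Total population, `> 0`.
#' @return A tibble with columns `S`, `I`, `R`, one row per equilibrium.
#' @export
sis_equilibria <- function(params, N0) {
  if (N0 <= 0) abort("`N0` must be positive.")
  eq <- tibble::tibble(S = 0, I = 0, R = N0)
  if (params$kV == 0) {
    S2 <- (params$gamma + params$kT) / params$beta
    if (S2 <= N0)
      eq <- dplyr::bind_rows(eq, tibble::tibble(S = S2, I = 0, R = N0 - S2))
  }
  eq
}

#' Classify the initial SIR regime
#'
#' Compares the initial susceptible level to the threshold
#' \eqn{\gamma/\beta}: case `"a"` (`S0` below threshold, infection decays
#' from the start), `"b"` (exactly at threshold), `"c"` (above threshold, the
#' infection first grows to an interior maximum).
#'
#' @param params A [sir_params()].
#' @param S0 Initial susceptible population, `>= 0`.
#' @param rel_tol Relative tolerance for the equality case.
#' @return One of `"a"`, `"b"`, `"c"`.
#' @export
classify_sir_case <- function(params, S0, rel_tol = 1e-12) {
  if (S0 < 0) abort("`S0` must be nonnegative.")
  thr <- params$gamma / params$beta
  if (abs(S0 - thr) <= rel_tol * max(S0, thr)) "b"
  else if (S0 < thr) "a"
  else "c"
}

#' Average infectious period in days
#'
#' Converts a recovery rate given per year to the mean infectious period in
#' days, using a 365-day year (e.g. `gamma = 50.1`/year gives 7.29 days).
#'
#' @param gamma Recovery rate (1/year).
#' @return Period in days, `365/gamma`.
#' @export
infectious_period_days <- function(gamma) {
  if (any(gamma <= 0)) abort("`gamma` must be positive.")
  365 / gamma
}
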