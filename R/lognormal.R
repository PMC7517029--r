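# The log-normal reference family: the maximum-dissipation width, the
# reference infection curve, its mode/inflection geometry, density moments
# and closed-form entropy.  Convention throughout: mu = ln(Dr) + sigma^2, so
# the reference peak time Dr is the *mode* of the t-domain curve.

#' Maximum-dissipation width of the log-normal reference
#'
#' The width at which the reference entropy's production rate is extremal
#' for entropy order `eta`:
#' \deqn{\sigma_r(\eta) = 1/\sqrt{2\eta},}
#' giving the classical \eqn{\sigma_r = 1/\sqrt 6 \approx 0.408} at
#' `eta = 3` and \eqn{1/\sqrt 2} at `eta = 1`.
#'
#' @param eta Entropy order, `> 0`.
#' @return The width \eqn{\sigma_r}.
#' @export
sigma_max_dissipation <- function(eta) {
  if (any(eta <= 0)) abort("`eta` must be positive.")
  1 / sqrt(2 * eta)
}

#' Log-normal reference curve parameters
#'
#' @param Dr Reference peak (mode) time, `> 0`.
#' @param sigma Width; defaults to the maximum-dissipation value for `eta`.
#' @param eta Entropy order, `> 0`.
#' @param I0 Initial-scale factor, `> 0`.
#' @return A list of class `lognormal_ref` with the derived location
#'   `mu = log(Dr) + sigma^2` (so that the mode is exactly `Dr`).
#' @export
lognormal_ref <- function(Dr = 1, sigma = NULL, eta = 3, I0 = 1) {
  if (Dr <= 0 || eta <= 0 || I0 <= 0)
    abort("`Dr`, `eta` and `I0` must be positive.")
  sigma <- sigma %||% sigma_max_dissipation(eta)
  if (sigma <= 0) abort("`sigma` must be positive.")
  structure(list(Dr = Dr, sigma = sigma, eta = eta, I0 = I0,
                 mu = log(Dr) + sigma^2),
            class = "lognormal_ref")
}

#' Reference infection curve
#'
#' The log-normal "infection reference evolution"
#' \deqn{I_r(t) = \sigma_r^2 I_0\, t^{-1}
#'       \exp\!\left(-\frac{(\ln t - \mu_r)^2}{2\sigma_r^2}\right),}
#' whose prefactor equals \eqn{k/(\sqrt{2\pi}\sigma_r)} with
#' \eqn{k = \sqrt{2\pi}\,\sigma_r^3 I_0} — the constant that identifies the
#' curve with the Gibrat closed form at the peak.
#'
#' @param ref A [lognormal_ref()].
#' @param t Times, `> 0` (vectorized).
#' @return Curve values \eqn{I_r(t)}.
#' @export
reference_curve <- function(ref, t) {
  stopifnot(inherits(ref, "lognormal_ref"))
  if (any(t <= 0)) abort("`t` must be positive.")
  ref$sigma^2 * ref$I0 / t * exp(-(log(t) - ref$mu)^2 / (2 * ref$sigma^2))
}

#' Mode and inflection time of the reference curve
#'
#' The mode is \eqn{D_r = e^{\mu - \sigma^2}}.  Writing
#' \eqn{\ln t = \mu + \sigma^2 v}, the zeros of the curve's second
#' derivative solve the quadratic \eqn{(1+v)^2 + (1+v) - 1/\sigma^2 = 0};
#' the preceding (rising-branch) inflection takes the smaller root
#' \eqn{1 + v_L = (-1 - \sqrt{1 + 4/\sigma^2})/2}, giving
#' \eqn{L_r = e^{\mu + \sigma^2 v_L} < D_r}.  At \eqn{\sigma^2 = 1/6} the
#' ratio is \eqn{D_r/L_r = e^{1/2} \approx 1.6487}.
#'
#' @param ref A [lognormal_ref()].
#' @return A one-row tibble with `Dr` and `Lr`.
#' @export
mode_and_inflection <- function(ref) {
  stopifnot(inherits(ref, "lognormal_ref"))
  s2 <- ref$sigma^2
  Dr <- exp(ref$mu - s2)
  vL <- (-1 - sqrt(1 + 4 / s2)) / 2 - 1
  Lr <- exp(ref$mu + s2 * vL)
  tibble::tibble(Dr = Dr, Lr = Lr)
}

#' Peak-to-inflection infection ratio of the reference curve
#'
#' \eqn{I_r(D_r)/I_r(L_r)}; analytically \eqn{e^{9\sigma^2/2}} for the
#' rising-branch inflection, which at the `eta = 3` maximum-dissipation
#' width \eqn{\sigma^2 = 1/6} equals \eqn{e^{3/4} \approx 2.1170}.
#'
#' @param ref A [lognormal_ref()].
#' @return The ratio (always `> 1`).
#' @export
peak_to_inflection_ratio <- function(ref) {
  mi <- mode_and_inflection(ref)
  reference_curve(ref, mi$Dr) / reference_curve(ref, mi$Lr)
}

#' Unit-mass log-normal density with mode `Dr`
#'
#' @param Dr Mode time, `> 0`.
#' @param sigma Width, `> 0`.
#' @param t Times, `> 0` (vectorized).
#' @return Density values; the density integrates to one over `(0, Inf)` and
#'   has its mode at `Dr` (location `mu = log(Dr) + sigma^2`).
#' @export
lognormal_pdf <- function(Dr, sigma, t) {
  if (Dr <= 0 || sigma <= 0) abort("`Dr` and `sigma` must be positive.")
  if (any(t <= 0)) abort("`t` must be positive.")
  dlnorm(t, meanlog = log(Dr) + sigma^2, sdlog = sigma)
}

#' Variance of the mode-parameterized log-normal
#'
#' With `mu = log(Dr) + sigma^2`, the variance
#' \eqn{(e^{\sigma^2}-1)e^{2\mu+\sigma^2}} becomes
#' \deqn{D_r^2 (e^{\sigma^2} - 1)\, e^{3\sigma^2},}
#' strictly increasing in `sigma` — which is what makes the
#' variance-matching width of [match_sigma_rmv()] unique.
#'
#' @inheritParams lognormal_pdf
#' @return The variance.
#' @export
lognormal_variance <- function(Dr, sigma) {
  if (any(Dr <= 0) || any(sigma <= 0))
    abort("`Dr` and `sigma` must be positive.")
  Dr^2 * (exp(sigma^2) - 1) * exp(3 * sigma^2)
}

#' Closed-form reference entropy
#'
#' The order-`eta` entropy of the log-normal reference family,
#' \deqn{S_{Ir}(\sigma, D_r, \eta) =
#'   \eta\left(\ln(\sqrt{2\pi}\,\sigma) + \eta(\ln D_r + \sigma^2)
#'   + \tfrac12\right).}
#' At `eta = 1` this is exactly the differential entropy
#' \eqn{\mu + 1/2 + \ln(\sqrt{2\pi}\sigma)} of [lognormal_pdf()], with
#' \eqn{\mu = \ln D_r + \sigma^2}; it is strictly increasing in `sigma`,
#' which makes the entropy-matching inversion of [match_sigma_rm()]
#' well posed.
#'
#' @param sigma Width, `> 0`.
#' @param Dr Mode time, `> 0`.
#' @param eta Entropy order, `> 0`.
#' @return Entropy in nats.
#' @export
reference_entropy_closed <- function(sigma, Dr, eta = 1) {
  if (any(sigma <= 0) || any(Dr <= 0) || any(eta <= 0))
    abort("`sigma`, `Dr` and `eta` must be positive.")
  eta * (log(sqrt(2 * pi) * sigma) + eta * (log(Dr) + sigma^2) + 0.5)
}
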