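# Matching a computed infection curve to the log-normal reference family:
# a reference peak time from the normalized entropy, a width by entropy
# equalization at fixed peak time, and a width by variance equalization.

#' Reference peak time from a normalized entropy
#'
#' Inverts the fixed-width (`sigma = 1/sqrt(2)`) reference-entropy relation
#' for the peak time:
#' \deqn{D_{rm} = e^{S_{In}(1) - 1}/\pi.}
#' The printed relation uses \eqn{\pi}; the closed-form entropy of the
#' log-normal family at \eqn{\sigma = 1/\sqrt 2} actually gives
#' \eqn{\sqrt\pi} in that position, so the alternative inversion
#' \eqn{e^{S-1}/\sqrt\pi} is available via `variant = "sqrt_pi"`.  Both
#' variants are exact inverses of their respective forward formulas; the
#' chosen variant is recorded by [match_reference()].
#'
#' @param S_In1 Normalized entropy at order 1 (nats).
#' @param variant `"printed"` (divide by pi, the default) or `"sqrt_pi"`.
#' @return The matched reference peak time.
#' @export
match_Drm <- function(S_In1, variant = c("printed", "sqrt_pi")) {
  variant <- match.arg(variant)
  exp(S_In1 - 1) / switch(variant, printed = pi, sqrt_pi = sqrt(pi))
}

# forward entropies inverted by match_Drm, used for the inversion identity
drm_forward_entropy <- function(Dr, variant = c("printed", "sqrt_pi")) {
  variant <- match.arg(variant)
  switch(variant,
         printed = log(pi) + log(Dr) + 1,
         sqrt_pi = 0.5 * log(pi) + log(Dr) + 1)
}

#' Entropy-matching width at fixed peak time
#'
#' Solves \eqn{S_{Ir}(\sigma, D, 1) = S_{In}(1)} for the width
#' \eqn{\sigma_{rm}}, holding the reference peak time fixed at the curve's
#' own peak time `D`.  The closed form [reference_entropy_closed()] is
#' strictly increasing in `sigma`, so the bracketed root on
#' `sigma` in `[1e-4, 10]` (expanded once to `[1e-6, 100]` if needed) is
#' unique.
#'
#' @param S_In1 Normalized entropy at order 1 (nats).
#' @param D Peak time to hold fixed, `> 0`.
#' @return The width `sigma_rm`.
#' @export
match_sigma_rm <- function(S_In1, D) {
  if (D <= 0) abort("`D` must be positive.")
  obj <- function(s) reference_entropy_closed(s, D, 1) - S_In1
  br <- c(1e-4, 10)
  if (obj(br[1L]) * obj(br[2L]) > 0) br <- c(1e-6, 100)
  if (obj(br[1L]) * obj(br[2L]) > 0)
    abort("`S_In1` is outside the attainable entropy range: no width solves it.")
  uniroot(obj, br, tol = 1e-12)$root
}

#' Variance of a normalized curve
#'
#' The second central moment
#' \eqn{\mathrm{var}(\omega) = \int_0^\infty \omega(t)\,
#'      (t - \int_0^\infty \omega\,t\,dt)^2 dt}
#' of a unit-mass curve.  A curve whose mass deviates from one by more than
#' `1e-8` is renormalized with a warning.
#'
#' @inheritParams shannon_entropy
#' @return The variance (nonnegative).
#' @export
curve_variance <- function(x, support = NULL, rel_tol = 1e-11) {
  cv <- resolve_curve(x, support)
  lo <- cv$support[1L]; hi <- cv$support[2L]
  mass <- quad_t(cv$I, lo, hi, rel_tol)$value
  if (!is.finite(mass) || mass <= 0)
    abort("curve mass is zero or divergent.")
  if (abs(mass - 1) > 1e-8) {
    warn(paste0("curve mass ", format(mass), " != 1; renormalizing."))
  }
  m1 <- quad_t(function(t) cv$I(t) * t, lo, hi, rel_tol)$value / mass
  if (!is.finite(m1)) abort("divergent first moment.")
  v <- quad_t(function(t) cv$I(t) * (t - m1)^2, lo, hi, rel_tol)$value / mass
  if (!is.finite(v)) abort("divergent second moment.")
  v
}

#' Variance-matching width at fixed peak time
#'
#' Solves \eqn{\mathrm{var} = D^2(e^{\sigma^2}-1)e^{3\sigma^2}} for
#' \eqn{\sigma_{rmv}}; the right-hand side is strictly increasing in
#' `sigma`, so the bracketed root is unique.
#'
#' @param var_target Target variance, `> 0`.
#' @param D Peak time to hold fixed, `> 0`.
#' @return The width `sigma_rmv`.
#' @export
match_sigma_rmv <- function(var_target, D) {
  if (var_target <= 0 || D <= 0)
    abort("`var_target` and `D` must be positive.")
  obj <- function(s) lognormal_variance(D, s) - var_target
  br <- c(1e-4, 10)
  if (obj(br[1L]) * obj(br[2L]) > 0) br <- c(1e-6, 100)
  if (obj(br[1L]) * obj(br[2L]) > 0)
    abort("`var_target` is outside the attainable range on the bracket.")
  uniroot(obj, br, tol = 1e-14)$root
}

#' Match an infection curve to the log-normal reference family
#'
#' Full matching pipeline: detect the peak time `D`, compute the normalized
#' order-1 entropy \eqn{S_{In}(1)}, invert it for the entropy-matched
#' reference peak time \eqn{D_{rm}} ([match_Drm()]), solve for the
#' entropy-matching width \eqn{\sigma_{rm}} at fixed `D`
#' ([match_sigma_rm()]), and solve for the variance-matching width
#' \eqn{\sigma_{rmv}} from the normalized curve's variance
#' ([match_sigma_rmv()]).
#'
#' @inheritParams shannon_entropy
#' @inheritParams match_Drm
#' @return An object of class `epi_match` (see [tidy.epi_match()] and
#'   [glance.epi_match()]) with fields `D`, `L`, `S_In1`, `D_rm`,
#'   `sigma_rm`, `sigma_rmv`, `var_In` and `variant`.
#' @export
#' @examples
#' m <- match_reference(fixture_curve("gibrat", list(D = 1, L = exp(-0.5))))
#' glance(m)
match_reference <- function(x, support = NULL,
                            variant = c("printed", "sqrt_pi"),
                            rel_tol = 1e-11) {
  variant <- match.arg(variant)
  cv <- resolve_curve(x, support)
  feats <- if (inherits(x, c("epi_curve", "epi_trajectory")))
    transient_features(x)
  else transient_features(epi_curve(cv$I, cv$support))
  S_In1 <- normalized_entropy(x, eta = 1, support = support,
                              rel_tol = rel_tol)$value
  mass <- quad_t(cv$I, cv$support[1L], cv$support[2L], rel_tol)$value
  var_In <- suppressWarnings(
    curve_variance(function(t) cv$I(t) / mass, support = cv$support,
                   rel_tol = rel_tol))
  D <- feats$D
  structure(list(
    D = D, L = feats$L, I_D = feats$I_D, I_L = feats$I_L,
    found_D = feats$found_D, found_L = feats$found_L,
    S_In1 = S_In1,
    D_rm = match_Drm(S_In1, variant),
    sigma_rm = if (feats$found_D) match_sigma_rm(S_In1, D) else NA_real_,
    sigma_rmv = if (feats$found_D) match_sigma_rmv(var_In, D) else NA_real_,
    var_In = var_In, variant = variant),
    class = "epi_match")
}

#' @export
print.epi_match <- function(x, ...) {
  cat("<epi_match> log-normal reference match (variant:", x$variant, ")\n")
  print(glance(x))
  invisible(x)
}

#' Tidy a reference match
#'
#' @param x An `epi_match` from [match_reference()].
#' @param ... Unused.
#' @return A tibble with one row per matched quantity (`term`, `estimate`).
#' @method tidy epi_match
#' @export
tidy.epi_match <- function(x, ...) {
  tibble::tibble(
    term = c("D", "L", "I_D", "I_L", "S_In1", "D_rm", "sigma_rm",
             "sigma_rmv", "var_In"),
    estimate = c(x$D, x$L, x$I_D, x$I_L, x$S_In1, x$D_rm, x$sigma_rm,
                 x$sigma_rmv, x$var_In))
}

#' Glance at a reference match
#'
#' @inheritParams tidy.epi_match
#' @return A one-row tibble with all matched quantities and the inversion
#'   variant used.
#' @method glance epi_match
#' @export
glance.epi_match <- function(x, ...) {
  tibble::tibble(D = x$D, L = x$L, S_In1 = x$S_In1, D_rm = x$D_rm,
                 sigma_rm = x$sigma_rm, sigma_rmv = x$sigma_rmv,
                 var_In = x$var_In, variant = x$variant)
}
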