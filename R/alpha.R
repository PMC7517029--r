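#' Driving-coefficient specification
#'
#' The first-order infection model \eqn{\dot I(t) = \alpha(t) I(t)} is driven
#' by a time-varying per-capita growth rate of the factorized form
#' \deqn{\alpha(t) = -c \, \ln(g(t)/E) / h(t),}
#' where `g` crosses the threshold `E` exactly at the infection maximum and
#' `h` sets the time scaling.  Multi-compartment models (SIR, controlled SIS)
#' can be cast in the same form, which is what makes the peak/inflection
#' theory of this package apply to them.
#'
#' @param c Positive scale constant (1/time).
#' @param E Positive threshold, in the units of `g`.
#' @param g,h Vectorized functions of time, nonnegative and differentiable on
#'   `(0, Inf)` with `g(t) > 0` and `h(t) > 0` for `t > 0`.
#'
#' @return An object of class `alpha_spec`.
#' @seealso [gibrat_alpha()] for the log-normal (Gibrat) special case,
#'   [alpha_eval()], [alpha_peak_preconditions()].
#' @export
#' @examples
#' sp <- alpha_spec(c = 6, E = 1, g = identity, h = identity)
#' alpha_eval(sp, 1)            # zero at the peak time
alpha_spec <- function(c, E, g, h) {
  stopifnot(is.function(g), is.function(h))
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    abort("`c` must be a single positive number.")
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0)
    abort("`E` must be a single positive number.")
  structure(list(c = c, E = E, g = g, h = h), class = "alpha_spec")
}

#' @export
print.alpha_spec <- function(x, ...) {
  cat("<alpha_spec> alpha(t) = -c * ln(g(t)/E) / h(t)\n")
  cat("  c =", format(x$c), "  E =", format(x$E), "\n")
  invisible(x)
}

#' Evaluate a driving coefficient
#'
#' Evaluates \eqn{\alpha(t) = -c\,\ln(g(t)/E)/h(t)}.  At `t = 0` the
#' one-sided limit is estimated numerically from a sequence of shrinking
#' evaluation points; `Inf` is returned for the (common) divergent case such
#' as the Gibrat coefficient, for which \eqn{\alpha(0^+) = +\infty}.
#'
#' @param spec An [alpha_spec()].
#' @param t Time(s), `>= 0`.
#' @return Numeric vector of \eqn{\alpha(t)} values.
#' @export
alpha_eval <- function(spec, t) {
  stopifnot(inherits(spec, "alpha_spec"))
  if (any(t < 0)) abort("`t` must be nonnegative.")
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    tv <- t[pos]
    gv <- spec$g(tv)
    hv <- spec$h(tv)
    lg <- log(gv / spec$E)
    bad <- hv == 0 & lg != 0
    if (any(bad))
      abort(paste0("alpha(t) is singular at t = ", format(tv[bad][1]),
                   ": h(t) = 0 with ln(g(t)/E) != 0."))
    val <- -spec$c * lg / hv
    val[hv == 0 & lg == 0] <- NaN   # genuine 0/0, needs alpha_factorization
    out[pos] <- val
  }
  if (any(!pos)) out[!pos] <- alpha_limit_at_zero(spec)
  out
}

# one-sided limit of alpha at t = 0+, estimated on a geometric sequence
alpha_limit_at_zero <- function(spec) {
  ts <- 10^seq(-6, -10, by = -1)
  vals <- vapply(ts, function(ti)
    -spec$c * log(spec$g(ti) / spec$E) / spec$h(ti), numeric(1))
  if (all(is.finite(vals))) {
    if (abs(vals[length(vals)] - vals[length(vals) - 1L]) <=
        1e-6 * (1 + abs(vals[length(vals)])))
      return(vals[length(vals)])
    # diverging magnitude: report the signed infinity
    if (all(diff(abs(vals)) > 0)) return(sign(vals[length(vals)]) * Inf)
  }
  vals[length(vals)]
}

#' Gibrat driving coefficient from peak and inflection times
#'
#' Builds the driving coefficient \eqn{\alpha(t) = -c \ln(t/D)/t} whose
#' solution is the Gibrat-type curve
#' \eqn{I(t) \propto \exp(-(c/2)\ln^2(t/D))} — shape-identical to a
#' log-normal density with \eqn{\sigma^2 = 1/c}.  The scale constant is fixed
#' by the requested peak time `D` and preceding inflection time `L` through
#' \deqn{c = \frac{1 - \ln(L/D)}{\ln^2(L/D)},}
#' which depends only on the ratio `L/D`.
#'
#' @param D Peak time, `> 0`.
#' @param L Inflection time, `0 < L < D`.
#' @return An [alpha_spec()] with `g = h = identity` and `E = D`; the derived
#'   constant is available as `$c` and satisfies `c * sigma^2 = 1` with the
#'   log-normal width `sigma^2 = 1/c`.
#' @export
#' @examples
#' gibrat_alpha(D = 1, L = exp(-0.5))$c   # 6
gibrat_alpha <- function(D, L) {
  if (!is.numeric(D) || !is.numeric(L) || D <= 0 || L <= 0)
    abort("`D` and `L` must be positive.")
  if (L >= D) abort("the inflection time `L` must precede the peak time `D`.")
  x <- log(L / D)
  c <- (1 - x) / x^2
  structure(list(c = c, E = D, g = identity, h = identity,
                 D = D, L = L, sigma2 = 1 / c),
            class = c("gibrat_alpha", "alpha_spec"))
}

#' Gibrat model parameters
#'
#' Convenience wrapper bundling the Gibrat driving coefficient with a peak
#' value, for use with [simulate_epidemic()] and [infection_closed_form()].
#'
#' @inheritParams gibrat_alpha
#' @param I_peak Infection value at the peak time `D`, `> 0`.
#' @return A list of class `gibrat_params` with elements `D`, `L`, `c`,
#'   `sigma2` and `I_peak`.
#' @export
gibrat_params <- function(D = 1, L = D * exp(-0.5), I_peak = 1) {
  spec <- gibrat_alpha(D, L)
  if (I_peak <= 0) abort("`I_peak` must be positive.")
  structure(list(D = D, L = L, c = spec$c, sigma2 = spec$sigma2,
                 I_peak = I_peak),
            class = "gibrat_params")
}

#' Closed-form Gibrat infection curve
#'
#' The solution of \eqn{\dot I = \alpha(t) I} with the Gibrat coefficient,
#' anchored at its peak value:
#' \deqn{I(t) = I_{peak} \exp\left(-\tfrac{c}{2}\ln^2(t/D)\right).}
#' Anchoring at the peak (rather than at \eqn{I(0^+)}, which is zero) keeps
#' the normalization finite; it is the same normalization that identifies the
#' curve with the log-normal reference of [reference_curve()].
#'
#' @param params A [gibrat_params()].
#' @param t Times, `> 0` (vectorized).
#' @return Infection values `I(t)`.
#' @export
infection_closed_form <- function(params, t) {
  stopifnot(inherits(params, "gibrat_params"))
  if (any(t <= 0)) abort("`t` must be positive.")
  params$I_peak * exp(-(params$c / 2) * log(t / params$D)^2)
}

#' Recover the time-scaling factor of a driving coefficient
#'
#' Given a driving coefficient `alpha` and a chosen threshold function `g`
#' with `g(t_zero) = E` at the infection-maximum time `t_zero`, returns the
#' factor \eqn{h(t) = -c\,\ln(g(t)/E)/\alpha(t)} completing the factorization
#' \eqn{\alpha = -c\ln(g/E)/h}.  The removable 0/0 singularity at `t_zero`
#' is filled with the L'Hopital limit
#' \eqn{h(t_{zero}) = c\, g'(t_{zero}) / (E\, |\alpha'(t_{zero})|)} computed
#' with central finite differences.
#'
#' @param alpha Function of time (the driving coefficient).
#' @param g Continuous increasing function with `g(t_zero) = E`.
#' @param E Threshold value.
#' @param c Positive scale constant.
#' @param t_zero Time at which `alpha` vanishes (the infection maximum).
#' @param tol Relative window around `t_zero` treated as the singular zone.
#' @return A function of time evaluating `h(t)`.
#' @export
alpha_factorization <- function(alpha, g, E, c, t_zero, tol = 1e-7) {
  stopifnot(is.function(alpha), is.function(g))
  if (abs(g(t_zero) - E) > 1e-8 * abs(E))
    abort("`g(t_zero)` must equal `E` for the factorization to close.")
  if (abs(alpha(t_zero)) > 1e-6 * max(1, abs(alpha(t_zero / 2))))
    abort("`alpha(t_zero)` must vanish (t_zero is the infection maximum).")
  dd <- t_zero * 1e-6
  dalpha <- (alpha(t_zero + dd) - alpha(t_zero - dd)) / (2 * dd)
  dg     <- (g(t_zero + dd) - g(t_zero - dd)) / (2 * dd)
  h_limit <- c * dg / (E * abs(dalpha))
  window <- tol * t_zero
  function(t) {
    out <- numeric(length(t))
    near <- abs(t - t_zero) <= window
    if (any(!near)) {
      tv <- t[!near]
      av <- alpha(tv)
      if (any(av == 0))
        abort("alpha vanishes away from `t_zero`: non-removable singularity.")
      out[!near] <- -c * log(g(tv) / E) / av
    }
    out[near] <- h_limit
    out
  }
}

#' Numerically check the peak/inflection preconditions of a driving coefficient
#'
#' Evaluates, on a dense grid, the four conditions under which the first-order
#' model \eqn{\dot I = \alpha(t) I} with
#' \eqn{\alpha = -c\ln(g/E)/h} is guaranteed to have a first infection
#' maximum `D` preceded by an inflection time `L < D`:
#'
#' 1. `g(t) < E` for all `t` before some `D <= upto` with `g(D) = E`;
#' 2. \eqn{g'(0) < g(0)\,(c\ln^2(g(0)/E) - |\ln(g(0)/E)|\,h'(0))/h(0)}
#'    (equivalent to \eqn{\alpha^2(0) + \dot\alpha(0) > 0}, i.e. the curve
#'    starts convex);
#' 3. `g(t) > 0` and `h(t) > 0` for `t > 0`;
#' 4. \eqn{\ln(g(0)/E)/h(0) \neq 0}.
#'
#' Functions singular at the origin (such as the Gibrat coefficient) are
#' probed at `t = 1e-8 * upto` in place of 0; divergence to the correct side
#' counts as satisfying the condition.
#'
#' @param spec An [alpha_spec()].
#' @param upto Upper end of the time range scanned.
#' @param n Grid size for the scan.
#' @return A one-row tibble with logical columns `cond1` to `cond4`, their
#'   conjunction `all_hold`, and the located threshold-crossing time `D`.
#' @export
alpha_peak_preconditions <- function(spec, upto, n = 4001L) {
  stopifnot(inherits(spec, "alpha_spec"), upto > 0)
  t0 <- 1e-8 * upto
  tt <- seq(t0, upto, length.out = n)
  gv <- spec$g(tt)
  hv <- spec$h(tt)
  E <- spec$E

  # condition 1: g rises through E at some D, staying below before it
  cross <- which(gv >= E)
  if (length(cross) == 0L) {
    cond1 <- FALSE; D <- NA_real_
  } else {
    i <- cross[1L]
    D <- if (i == 1L) tt[1L] else
      uniroot(function(t) spec$g(t) - E, c(tt[i - 1L], tt[i]),
              tol = 1e-12 * upto)$root
    cond1 <- i > 1L && all(gv[seq_len(i - 1L)] < E)
  }

  # condition 3: positivity away from the origin
  cond3 <- all(gv > 0) && all(hv > 0)

  # conditions 2 and 4 are evaluated at the origin proxy t0
  dd <- t0 / 2
  dg0 <- (spec$g(t0 + dd) - spec$g(t0 - dd)) / (2 * dd)
  dh0 <- (spec$h(t0 + dd) - spec$h(t0 - dd)) / (2 * dd)
  g0 <- spec$g(t0); h0 <- spec$h(t0)
  lg0 <- log(g0 / E)
  rhs <- g0 * (spec$c * lg0^2 - abs(lg0) * dh0) / h0
  cond2 <- is.nan(rhs) || dg0 < rhs     # divergent rhs (+Inf) => satisfied
  if (is.finite(rhs)) cond2 <- dg0 < rhs
  ratio0 <- lg0 / h0
  cond4 <- !is.finite(ratio0) || abs(ratio0) > 0

  tibble::tibble(cond1 = cond1, cond2 = cond2, cond3 = cond3, cond4 = cond4,
                 all_hold = cond1 && cond2 && cond3 && cond4, D = D)
}
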