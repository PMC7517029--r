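# Transient-feature detection: first infection maximum D, preceding
# inflection L, alternation of derivative zeros, and cut times after which
# the curve and its derivatives stay below prescribed thresholds.

# all sign-change roots of fun on [lo, hi], bracketed on an n-point grid and
# refined with Brent's method; grazing zeros (no sign change) are ignored.
sign_change_roots <- function(fun, lo, hi, n = 4001L, first_only = FALSE) {
  tt <- seq(lo, hi, length.out = n)
  v <- fun(tt)
  roots <- numeric(0)
  i <- 1L
  while (i < n) {
    vi <- v[i]; vj <- v[i + 1L]
    if (is.finite(vi) && is.finite(vj) && vi * vj < 0) {
      r <- uniroot(fun, c(tt[i], tt[i + 1L]),
                   f.lower = vi, f.upper = vj,
                   tol = 1e-10 * max(abs(hi), 1e-12))$root
      roots <- c(roots, r)
      if (first_only) return(roots)
    } else if (vi == 0 && i > 1L && v[i - 1L] * vj < 0) {
      roots <- c(roots, tt[i])            # exact grid zero with sign change
      if (first_only) return(roots)
    }
    i <- i + 1L
  }
  roots
}

#' First infection maximum
#'
#' Locates the first time `D` at which \eqn{\dot I(D) = 0} with
#' \eqn{\ddot I(D) < 0} — the epidemic peak.  The first derivative is
#' scanned for a sign change on a dense grid (at least 2000 nodes across the
#' support) and the bracketed root refined to a relative time tolerance of
#' `1e-10`.  A grazing zero of \eqn{\dot I} without sign change does not
#' count, and a monotone curve yields `found = FALSE` (not an error).
#'
#' @param x An `epi_trajectory` or `epi_curve`.
#' @param n Scan grid size.
#' @return A one-row tibble with `found`, `D` and `I_D`.
#' @export
find_first_maximum <- function(x, n = 4001L) {
  f <- curve_funs(x)
  roots <- sign_change_roots(f$dI, f$support[1L], f$support[2L], n)
  for (r in roots) {
    if (f$d2I(r) < 0)
      return(tibble::tibble(found = TRUE, D = r, I_D = f$I(r)))
  }
  tibble::tibble(found = FALSE, D = NA_real_, I_D = NA_real_)
}

#' First inflection of the infection curve
#'
#' Locates the first time `L` in `(t0, upper)` at which \eqn{\ddot I(L) = 0}
#' *with a sign change* — the sign-change test distinguishes a true
#' inflection from a mere undulation point, where the second derivative
#' touches zero without changing sign.
#'
#' @inheritParams find_first_maximum
#' @param upper Upper end of the search window; defaults to the detected
#'   peak time `D` when one exists, else the end of the support.
#' @return A one-row tibble with `found`, `L` and `I_L`.
#' @export
find_first_inflection <- function(x, upper = NULL, n = 4001L) {
  f <- curve_funs(x)
  if (is.null(upper)) {
    mx <- find_first_maximum(x, n)
    upper <- if (mx$found) mx$D else f$support[2L]
  }
  roots <- sign_change_roots(f$d2I, f$support[1L], upper, n,
                             first_only = TRUE)
  if (length(roots) == 0L)
    return(tibble::tibble(found = FALSE, L = NA_real_, I_L = NA_real_))
  tibble::tibble(found = TRUE, L = roots[1L], I_L = f$I(roots[1L]))
}

#' Peak and inflection features of an infection curve
#'
#' Convenience wrapper combining [find_first_maximum()] and
#' [find_first_inflection()]; when both are found the invariant
#' `0 < L < D` holds.
#'
#' @inheritParams find_first_maximum
#' @return A one-row tibble with `found_D`, `found_L`, `D`, `L`, `I_D`,
#'   `I_L`.
#' @export
transient_features <- function(x, n = 4001L) {
  mx <- find_first_maximum(x, n)
  fl <- find_first_inflection(x, upper = if (mx$found) mx$D else NULL, n = n)
  tibble::tibble(found_D = mx$found, found_L = fl$found,
                 D = mx$D, L = fl$L, I_D = mx$I_D, I_L = fl$I_L)
}

#' Alternation of derivative zeros
#'
#' Collects the sign-change zeros of \eqn{\dot I} (times of relative
#' extrema, set `DS`) and of \eqn{\ddot I} (inflection times, set `LS`)
#' across the support, and checks the alternation structure: between
#' consecutive members of one set lies exactly one member of the other, and
#' the first inflection precedes the first extremum.  A curve with no zeros
#' alternates vacuously.
#'
#' @inheritParams find_first_maximum
#' @return A list with numeric vectors `DS` and `LS` and logical
#'   `alternates`.
#' @export
check_alternation <- function(x, n = 4001L) {
  f <- curve_funs(x)
  DS <- sign_change_roots(f$dI, f$support[1L], f$support[2L], n)
  LS <- sign_change_roots(f$d2I, f$support[1L], f$support[2L], n)
  lab <- c(rep("D", length(DS)), rep("L", length(LS)))
  ord <- order(c(DS, LS))
  lab <- lab[ord]
  alternates <-
    if (length(lab) == 0L) TRUE
    else all(utils::head(lab, -1L) != utils::tail(lab, -1L)) &&
      (length(DS) == 0L || length(LS) == 0L || lab[1L] == "L")
  list(DS = DS, LS = LS, alternates = alternates)
}

#' Cut times of an infection curve
#'
#' For `i = 1, 2, 3`, the cut time \eqn{t_{Ii}} is the earliest time after
#' which the magnitude of the \eqn{(i-1)}-th derivative of `I` stays at or
#' below \eqn{k_i \varepsilon} — a practical definition of when the curve,
#' its slope, and its curvature have effectively settled.  The "for all
#' later times" clause is necessarily enforced only up to the simulated
#' horizon, which is recorded in the result: the scan runs from the horizon
#' backwards to the last threshold violation and refines the crossing.
#'
#' @inheritParams find_first_maximum
#' @param k Numeric length-3 thresholds multipliers, each `>= 1`.
#' @param eps Base tolerance in `(0, 1)`.
#' @return A one-row tibble with `tI1`, `tI2`, `tI3` (NA when the condition
#'   never holds on the horizon), `k1`, `k2`, `k3`, `eps` and `horizon`.
#' @export
cut_times <- function(x, k = c(1, 1, 1), eps = 0.01, n = 4001L) {
  if (!(eps > 0 && eps < 1)) abort("`eps` must lie in (0, 1).")
  if (length(k) != 3L || any(k < 1)) abort("`k` must be three values >= 1.")
  f <- curve_funs(x)
  lo <- f$support[1L]; hi <- f$support[2L]
  tt <- seq(lo, hi, length.out = n)
  funs <- list(f$I, f$dI, f$d2I)
  out <- purrr::map_dbl(1:3, function(i) {
    thr <- k[i] * eps
    v <- abs(funs[[i]](tt))
    viol <- which(v > thr)
    if (length(viol) == 0L) return(lo)
    j <- viol[length(viol)]
    if (j == n) return(NA_real_)
    uniroot(function(t) abs(funs[[i]](t)) - thr, c(tt[j], tt[j + 1L]),
            tol = 1e-10 * max(abs(hi), 1e-12))$root
  })
  tibble::tibble(tI1 = out[1L], tI2 = out[2L], tI3 = out[3L],
                 k1 = k[1L], k2 = k[2L], k3 = k[3L],
                 eps = eps, horizon = hi)
}

#' Interior-maximum preconditions for the controlled SIS model
#'
#' Checks the three sufficient conditions under which the controlled SIS
#' infection curve rises to an interior maximum (reached when the
#' susceptibles fall to \eqn{(\gamma + k_T)/\beta}) preceded by a strict
#' inflection:
#'
#' 1. \eqn{S_0 > (\gamma + k_T)/\beta} (the infection initially grows);
#' 2. \eqn{I_0 < 1 + (k_T + k_V S_0)/\gamma};
#' 3. \eqn{\dot I_0 > \beta |\dot S_0| I_0 / (\beta S_0 - \gamma - k_T)}
#'    (the curve starts convex, \eqn{\ddot I_0 > 0}).
#'
#' @param params A [sis_params()].
#' @param init Named numeric vector with at least `S` and `I` (and
#'   optionally `R`).
#' @return A one-row tibble with the three condition booleans, their
#'   conjunction `all_hold`, the thresholds `S_threshold`, `I_threshold`,
#'   `dI0_threshold`, and the derived rates `dI0`, `dS0`.
#' @export
sis_peak_preconditions <- function(params, init) {
  stopifnot(inherits(params, "sis_params"))
  S0 <- init[["S"]]; I0 <- init[["I"]]
  if (S0 < 0 || I0 < 0) abort("initial state must be nonnegative.")
  b <- params$beta; g <- params$gamma; kV <- params$kV; kT <- params$kT
  S_thr <- (g + kT) / b
  I_thr <- 1 + (kT + kV * S0) / g
  dI0 <- (b * S0 - g - kT) * I0
  dS0 <- g * I0 - b * S0 * I0 - kV * S0
  denom <- b * S0 - g - kT
  dI0_thr <- if (denom > 0) b * abs(dS0) * I0 / denom else NA_real_
  tibble::tibble(
    cond1 = S0 > S_thr,
    cond2 = I0 < I_thr,
    cond3 = denom > 0 && dI0 > dI0_thr,
    all_hold = S0 > S_thr && I0 < I_thr && denom > 0 && dI0 > dI0_thr,
    S_threshold = S_thr, I_threshold = I_thr, dI0_threshold = dI0_thr,
    dI0 = dI0, dS0 = dS0)
}
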