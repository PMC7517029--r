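#' Analytic infection curve
#'
#' Wraps a closed-form infection curve together with its first two time
#' derivatives so that the transient-detection and entropy machinery can use
#' it interchangeably with a simulated trajectory.  Missing derivatives are
#' filled in by central finite differences (step `1e-6` of the support
#' width), which is accurate enough for bracketing but not for the tightest
#' oracle tests — supply analytic derivatives where available.
#'
#' @param I Function of time, the infection curve (vectorized, nonnegative).
#' @param support Numeric `c(lo, hi)`, `0 < lo < hi`, on which the curve is
#'   evaluated.
#' @param dI,d2I Optional derivative functions.
#' @return An object of class `epi_curve`.
#' @export
epi_curve <- function(I, support, dI = NULL, d2I = NULL) {
  stopifnot(is.function(I), length(support) == 2L, support[1L] > 0,
            support[2L] > support[1L])
  h <- 1e-6 * diff(support)
  if (is.null(dI)) dI <- function(t) (I(t + h) - I(t - h)) / (2 * h)
  if (is.null(d2I)) d2I <- function(t) (I(t + h) - 2 * I(t) + I(t - h)) / h^2
  structure(list(I = I, dI = dI, d2I = d2I, support = as.numeric(support)),
            class = "epi_curve")
}

#' @export
curve_funs.epi_curve <- function(x) x[c("I", "dI", "d2I", "support")]

#' @export
print.epi_curve <- function(x, ...) {
  cat("<epi_curve> support [", format(x$support[1L]), ",",
      format(x$support[2L]), "]\n")
  invisible(x)
}

#' Sample an infection curve onto a tibble
#'
#' @param curve An `epi_curve`.
#' @param n Number of equally spaced sample times across the support.
#' @return A tibble with columns `t` and `I`.
#' @export
sample_curve <- function(curve, n = 2001L) {
  f <- curve_funs(curve)
  t <- seq(f$support[1L], f$support[2L], length.out = n)
  tibble::tibble(t = t, I = f$I(t))
}

#' Fixture curve generators
#'
#' Deterministic closed-form curves used throughout the package's tests and
#' experiments:
#'
#' * `"gibrat"`: \eqn{I(t) = I_{peak} e^{-(c/2)\ln^2(t/D)}} with analytic
#'   derivatives through \eqn{\alpha(t) = -c\ln(t/D)/t}; `params` are passed
#'   to [gibrat_params()] (`D`, `L`, `I_peak`).
#' * `"lognormal"`: the unit-mass log-normal density with mode `Dr` and
#'   width `sigma` ([lognormal_pdf()]), scaled by `I0`.
#' * `"oscillatory"`: the solution \eqn{I = I_0 e^{(a/\omega)\sin\omega t}}
#'   of \eqn{\dot I = a\cos(\omega t) I}; its derivative zeros strictly
#'   interleave, which exercises the peak/inflection alternation check.
#' * `"perturbed"`: a base curve times \eqn{(1 + A\,p(t))} where `p` is a
#'   smooth random Fourier bump with `max |p| <= 1`, drawn reproducibly from
#'   `seed`; the relative amplitude `A < 1` guarantees positivity.
#'
#' @param kind One of `"gibrat"`, `"lognormal"`, `"oscillatory"`,
#'   `"perturbed"`.
#' @param params Named list of parameters for the chosen kind (see Details).
#' @param seed Integer seed (used by `"perturbed"` only).
#' @return An [epi_curve()] with analytic derivatives.
#' @export
#' @examples
#' fx <- fixture_curve("gibrat", list(D = 1, L = exp(-0.5)))
#' find_first_maximum(fx)$D
fixture_curve <- function(kind = c("gibrat", "lognormal", "oscillatory",
                                   "perturbed"),
                          params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- params
  switch(kind,
    gibrat = {
      gp <- gibrat_params(D = p$D %||% 1, L = p$L %||% ((p$D %||% 1) * exp(-0.5)),
                          I_peak = p$I_peak %||% 1)
      al <- function(t) -gp$c * log(t / gp$D) / t
      dal <- function(t) -gp$c * (1 - log(t / gp$D)) / t^2
      If <- function(t) infection_closed_form(gp, t)
      epi_curve(If,
                support = p$support %||% c(1e-6 * gp$D, 50 * gp$D),
                dI = function(t) al(t) * If(t),
                d2I = function(t) (dal(t) + al(t)^2) * If(t))
    },
    lognormal = {
      Dr <- p$Dr %||% 1; sigma <- p$sigma %||% sigma_max_dissipation(3)
      I0 <- p$I0 %||% 1
      mu <- log(Dr) + sigma^2
      If <- function(t) I0 * dlnorm(t, meanlog = mu, sdlog = sigma)
      lr <- function(t) -(1 + (log(t) - mu) / sigma^2) / t   # d log f / dt
      dlr <- function(t) (1 + (log(t) - mu) / sigma^2 - 1 / sigma^2) / t^2
      epi_curve(If,
                support = p$support %||%
                  exp(mu + c(-10, 10) * sigma),
                dI = function(t) lr(t) * If(t),
                d2I = function(t) (dlr(t) + lr(t)^2) * If(t))
    },
    oscillatory = {
      a <- p$a %||% 1; omega <- p$omega %||% (2 * pi); I0 <- p$I0 %||% 1
      If <- function(t) I0 * exp((a / omega) * sin(omega * t))
      al <- function(t) a * cos(omega * t)
      dal <- function(t) -a * omega * sin(omega * t)
      epi_curve(If,
                support = p$support %||% c(1e-6, 3),
                dI = function(t) al(t) * If(t),
                d2I = function(t) (dal(t) + al(t)^2) * If(t))
    },
    perturbed = {
      base <- p$base %||% fixture_curve("lognormal")
      A <- p$amplitude %||% 1e-3
      if (A >= 1) abort("`amplitude` must be < 1 to keep the curve positive.")
      bf <- curve_funs(base)
      Tw <- diff(bf$support)
      set.seed(seed)
      w <- stats::runif(4L, 0.5, 1.5)
      phi <- stats::runif(4L, 0, 2 * pi)
      w <- w / sum(abs(w))          # max |p| <= 1
      om <- 2 * pi * (1:4) / Tw
      pfun <- function(t) colSums(w * sin(outer(om, t) + phi))
      dp <- function(t) colSums(w * om * cos(outer(om, t) + phi))
      d2p <- function(t) -colSums(w * om^2 * sin(outer(om, t) + phi))
      epi_curve(function(t) bf$I(t) * (1 + A * pfun(t)),
                support = bf$support,
                dI = function(t) bf$dI(t) * (1 + A * pfun(t)) +
                  bf$I(t) * A * dp(t),
                d2I = function(t) bf$d2I(t) * (1 + A * pfun(t)) +
                  2 * bf$dI(t) * A * dp(t) + bf$I(t) * A * d2p(t))
    })
}
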