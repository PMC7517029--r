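# Adaptive Dormand-Prince RK5(4) integrator with output clamped to a fixed
# grid.  No ODE-solver package is assumed; the right-hand sides here are
# tiny, so a pure-R stepper at rtol ~ 1e-10 is fast enough and the clamped
# grid (>= 2000 nodes) keeps the Hermite dense output far below the solver
# tolerance between nodes.

.dp_A <- matrix(c(
  0, 0, 0, 0, 0, 0,
  1/5, 0, 0, 0, 0, 0,
  3/40, 9/40, 0, 0, 0, 0,
  44/45, -56/15, 32/9, 0, 0, 0,
  19372/6561, -25360/2187, 64448/6561, -212/729, 0, 0,
  9017/3168, -355/33, 46732/5247, 49/176, -5103/18656, 0),
  nrow = 6, byrow = TRUE)
.dp_c <- c(0, 1/5, 3/10, 4/5, 8/9, 1)
.dp_b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)
.dp_b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)

rk45_grid <- function(f, y0, times, rtol = 1e-10, atol = 1e-12,
                      clip_floor = 0) {
  n <- length(times)
  d <- length(y0)
  Y <- matrix(NA_real_, n, d)
  Y[1L, ] <- y0
  y <- y0
  t <- times[1L]
  h <- (times[n] - times[1L]) / 100
  hmin <- (times[n] - times[1L]) * 1e-14
  k <- matrix(0, 7L, d)
  for (j in 2L:n) {
    tend <- times[j]
    while (t < tend) {
      h <- min(h, tend - t)
      k[1L, ] <- f(t, y)
      for (s in 2L:6L) {
        ys <- y + h * drop(.dp_A[s, 1:(s - 1)] %*% k[1:(s - 1), , drop = FALSE])
        k[s, ] <- f(t + .dp_c[s] * h, ys)
      }
      y5 <- y + h * drop(.dp_b5 %*% k[1:6, , drop = FALSE])
      k[7L, ] <- f(t + h, y5)
      y4 <- y + h * drop(.dp_b4 %*% k)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (err <= 1) {
        t <- t + h
        y <- y5
        if (clip_floor > 0) {
          neg <- y < 0
          if (any(neg)) {
            if (any(y < -clip_floor))
              abort(paste0("state went negative beyond tolerance at t = ",
                           format(t)))
            y[neg] <- 0
          }
        }
      }
      h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
      if (h < hmin)
        abort(paste0("step size underflow at t = ", format(t)))
    }
    Y[j, ] <- y
  }
  Y
}

#' Integrate an epidemic model
#'
#' Integrates the Gibrat first-order model, the SIR model, or the controlled
#' SIS model with an adaptive Runge-Kutta 5(4) scheme (relative tolerance
#' `1e-10`, absolute `1e-12` by default) and returns the solution on a dense
#' regular grid as an `epi_trajectory` tibble.  Between grid nodes the
#' trajectory can be evaluated by cubic Hermite interpolation using the
#' analytic right-hand side at the nodes (see [curve_funs()]), which is what
#' the peak/inflection root refinement relies on.
#'
#' For the Gibrat model the driving coefficient diverges at `t = 0`, so
#' integration starts at `t0 = 1e-6 * D` with the initial value supplied by
#' the closed form [infection_closed_form()].
#'
#' @param params A [gibrat_params()], [sir_params()] or [sis_params()].
#' @param init Named numeric vector of initial values, e.g.
#'   `c(S = 0.99, I = 0.01, R = 0)`.  Ignored for the Gibrat model.
#' @param horizon End time of the integration (years).
#' @param t0 Start time; defaults to 0 (SIR/SIS) or `1e-6 * D` (Gibrat).
#' @param n_out Number of output grid nodes (at least 2000 are kept so root
#'   bracketing on the grid is reliable).
#' @param rtol,atol Solver tolerances.
#' @return A tibble of class `epi_trajectory` with column `t` and one column
#'   per compartment; attributes carry the model, parameters and grid data.
#' @export
#' @examples
#' traj <- simulate_epidemic(sir_params(13065, 50.1),
#'                           c(S = 0.99, I = 0.01, R = 0), horizon = 0.05)
#' find_first_maximum(traj)
simulate_epidemic <- function(params, init = NULL, horizon, t0 = NULL,
                              n_out = 4001L, rtol = 1e-10, atol = 1e-12) {
  n_out <- max(as.integer(n_out), 2001L)
  if (inherits(params, "gibrat_params")) {
    t0 <- t0 %||% (1e-6 * params$D)
    if (t0 <= 0) abort("`t0` must be positive for the Gibrat model.")
    if (horizon <= t0) abort("`horizon` must exceed `t0`.")
    a <- gibrat_alpha(params$D, params$L)
    # the infection spans hundreds of orders of magnitude near t0, so the
    # ODE dI/dt = alpha(t) I is integrated in log space: d(ln I)/dt = alpha
    f <- function(t, y) -a$c * log(t / params$D) / t
    times <- seq(t0, horizon, length.out = n_out)
    y0 <- log(infection_closed_form(params, t0))
    Y <- rk45_grid(f, y0, times, rtol, atol)
    out <- tibble::tibble(t = times, I = exp(Y[, 1L]))
    model <- "gibrat"
    N0 <- NA_real_
  } else if (inherits(params, c("sir_params", "sis_params"))) {
    t0 <- t0 %||% 0
    if (horizon <= t0) abort("`horizon` must exceed `t0`.")
    if (is.null(init)) abort("`init` is required for SIR/SIS models.")
    y0 <- c(S = unname(init[["S"]]), I = unname(init[["I"]]),
            R = if ("R" %in% names(init)) unname(init[["R"]]) else 0)
    if (any(y0 < 0)) abort("initial state must be nonnegative.")
    N0 <- sum(y0)
    times <- seq(t0, horizon, length.out = n_out)
    if (inherits(params, "sir_params") && y0[["S"]] > 0) {
      # S decays multiplicatively over hundreds of orders of magnitude in
      # high-reproduction regimes; integrating ln S keeps it under relative
      # error control at any magnitude
      f <- function(t, y)
        c(-params$beta * y[2L],
          (params$beta * exp(y[1L]) - params$gamma) * y[2L],
          params$gamma * y[2L])
      Y <- rk45_grid(f, c(log(y0[["S"]]), y0[["I"]], y0[["R"]]),
                     times, rtol, atol)
      Y <- cbind(exp(Y[, 1L]), pmax(Y[, 2L], 0), Y[, 3L])
    } else {
      rhs <- if (inherits(params, "sir_params")) sir_rhs else sis_rhs
      f <- function(t, y) unname(rhs(params, y))
      Y <- rk45_grid(f, unname(y0), times, rtol, atol,
                     clip_floor = 1e-12 * N0)
    }
    out <- tibble::tibble(t = times, S = Y[, 1L], I = Y[, 2L], R = Y[, 3L])
    model <- if (inherits(params, "sir_params")) "sir" else "sis"
  } else {
    abort("unknown parameter object; use gibrat_params(), sir_params() or sis_params().")
  }
  structure(out,
            class = c("epi_trajectory", class(out)),
            model = model, params = params, N0 = N0,
            t0 = t0, horizon = horizon, rtol = rtol, atol = atol)
}

#' @export
print.epi_trajectory <- function(x, ...) {
  cat("<epi_trajectory> model:", attr(x, "model"),
      " t in [", format(attr(x, "t0")), ",", format(attr(x, "horizon")), "]\n")
  NextMethod()
}

# analytic state derivatives at arbitrary states, per model
traj_state_deriv <- function(model, params, S, I) {
  switch(model,
    sir = list(dS = -params$beta * S * I,
               dI = (params$beta * S - params$gamma) * I),
    sis = list(dS = params$gamma * I - params$beta * S * I - params$kV * S,
               dI = (params$beta * S - params$gamma - params$kT) * I),
    abort("internal: unknown model"))
}

# cubic Hermite interpolation on the trajectory grid
hermite_eval <- function(tt, y, dy, t) {
  i <- findInterval(t, tt, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(tt) - 1L)
  h <- tt[i + 1L] - tt[i]
  s <- (t - tt[i]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y[i] + h10 * h * dy[i] + h01 * y[i + 1L] + h11 * h * dy[i + 1L]
}

#' Functional view of an infection curve
#'
#' Returns the infection curve and its first two time derivatives as
#' functions of time, plus the support on which they are defined.  For a
#' simulated [simulate_epidemic()] trajectory the states are interpolated by
#' cubic Hermite polynomials anchored on the analytic right-hand side, and
#' the derivatives \eqn{\dot I, \ddot I} are evaluated analytically from the
#' interpolated states (not by differencing).  For an [epi_curve()] the
#' stored closed forms are used.
#'
#' @param x An `epi_trajectory` or `epi_curve`.
#' @return A list with functions `I`, `dI`, `d2I` (and `S` when a
#'   susceptible compartment exists) and the numeric `support = c(lo, hi)`.
#' @export
curve_funs <- function(x) UseMethod("curve_funs")

#' @export
curve_funs.epi_trajectory <- function(x) {
  model <- attr(x, "model")
  params <- attr(x, "params")
  tt <- x$t
  if (model == "gibrat") {
    al <- function(t) -params$c * log(t / params$D) / t
    dal <- function(t) -params$c * (1 - log(t / params$D)) / t^2
    # interpolate in log space, where the curve is a gentle parabola in ln t
    yg <- log(x$I)
    If <- function(t) exp(hermite_eval(tt, yg, al(tt), t))
    list(I = If,
         dI = function(t) al(t) * If(t),
         d2I = function(t) (dal(t) + al(t)^2) * If(t),
         support = c(tt[1L], tt[length(tt)]))
  } else {
    Sg <- x$S; Ig <- x$I
    dg <- traj_state_deriv(model, params, Sg, Ig)
    Sf <- function(t) hermite_eval(tt, Sg, dg$dS, t)
    If <- function(t) hermite_eval(tt, Ig, dg$dI, t)
    dIf <- function(t) {
      traj_state_deriv(model, params, Sf(t), If(t))$dI
    }
    d2If <- function(t) {
      S <- Sf(t); I <- If(t)
      d <- traj_state_deriv(model, params, S, I)
      lin <- if (model == "sir") params$beta * S - params$gamma
             else params$beta * S - params$gamma - params$kT
      params$beta * d$dS * I + lin * d$dI
    }
    list(I = If, dI = dIf, d2I = d2If, S = Sf,
         support = c(tt[1L], tt[length(tt)]))
  }
}

#' Driving coefficient of a simulated trajectory
#'
#' Recovers \eqn{\alpha(t) = \dot I(t)/I(t)} from the analytic right-hand
#' side of the integrated model: \eqn{\beta S(t) - \gamma} for SIR,
#' \eqn{\beta S(t) - \gamma - k_T} for the controlled SIS model, and
#' \eqn{-c \ln(t/D)/t} for the Gibrat model.
#'
#' @param traj An `epi_trajectory`.
#' @return A function of time; evaluating it where `I(t) = 0` is an error.
#' @export
alpha_from_trajectory <- function(traj) {
  stopifnot(inherits(traj, "epi_trajectory"))
  model <- attr(traj, "model")
  params <- attr(traj, "params")
  funs <- curve_funs(traj)
  function(t) {
    if (any(funs$I(t) <= 0))
      abort("I(t) must be positive where alpha is requested.")
    switch(model,
      gibrat = -params$c * log(t / params$D) / t,
      sir = params$beta * funs$S(t) - params$gamma,
      sis = params$beta * funs$S(t) - params$gamma - params$kT)
  }
}

#' Maximum conservation defect of a trajectory
#'
#' For SIR/SIS trajectories, the largest deviation of `S + I + R` from the
#' initial total population across the output grid.
#'
#' @param traj An `epi_trajectory` with all three compartments.
#' @return A single nonnegative number.
#' @export
conservation_defect <- function(traj) {
  stopifnot(inherits(traj, "epi_trajectory"))
  if (attr(traj, "model") == "gibrat")
    abort("the Gibrat model has no conservation law.")
  max(abs(traj$S + traj$I + traj$R - attr(traj, "N0")))
}
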