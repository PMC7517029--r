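# Experiment presets and the feature-extraction pipeline.  Time units are
# years throughout (rates per year); day conversions only happen at report
# time via infectious_period_days().

#' Built-in experiment presets
#'
#' Named parameter sets reproducing the package's standard numerical
#' experiments:
#'
#' * `"sis_demo"`: controlled SIS with `beta = 30`, `gamma = 50`, `kV = 1`,
#'   `kT = 50` (per year) and unnormalized initial conditions
#'   `S0 = 10, I0 = 0.2` that satisfy all three peak preconditions of
#'   [sis_peak_preconditions()].  (A unit total population cannot satisfy
#'   them for these rates, since the susceptible threshold is
#'   `(gamma + kT)/beta = 10/3`.)
#' * `"sis_no_peak"`: same rates with `S0` exactly at the threshold, so the
#'   initial infection derivative vanishes and no interior maximum exists.
#' * `"sis_uncontrolled"`: same rates with `kV = kT = 0` and a normalized
#'   population.
#' * `"sir_epidemic"`: SIR with `beta = 13065`, `gamma = 50.1` per year,
#'   `S0 = 0.99, I0 = 0.01` (one percent of a unit population initially
#'   infectious) — the above-threshold regime with an interior epidemic
#'   peak.
#' * `"sir_decay"`: same rates with `S0` below the threshold
#'   `gamma/beta ~ 0.003835`, so the infection decays from the start.
#' * `"gibrat_unit"`: the first-order Gibrat model with `D = 1`,
#'   `L = exp(-1/2)` (hence `c = 6`).
#'
#' @param name Preset name.
#' @return A list with elements `params`, `init`, `horizon`, `t0`.
#' @export
epi_preset <- function(name = c("sis_demo", "sis_no_peak",
                                "sis_uncontrolled", "sir_epidemic",
                                "sir_decay", "gibrat_unit")) {
  name <- match.arg(name)
  switch(name,
    sis_demo = list(
      params = sis_params(beta = 30, gamma = 50, kV = 1, kT = 50),
      init = c(S = 10, I = 0.2, R = 0), horizon = 0.5, t0 = 0),
    sis_no_peak = list(
      params = sis_params(beta = 30, gamma = 50, kV = 1, kT = 50),
      init = c(S = 100 / 30, I = 0.2, R = 0), horizon = 0.5, t0 = 0),
    sis_uncontrolled = list(
      params = sis_params(beta = 30, gamma = 50, kV = 0, kT = 0),
      init = c(S = 0.99, I = 0.01, R = 0), horizon = 0.5, t0 = 0),
    sir_epidemic = list(
      params = sir_params(beta = 13065, gamma = 50.1),
      init = c(S = 0.99, I = 0.01, R = 0), horizon = 0.25, t0 = 0),
    sir_decay = list(
      params = sir_params(beta = 13065, gamma = 50.1),
      init = c(S = 0.003, I = 0.5, R = 0.497), horizon = 1, t0 = 0),
    gibrat_unit = list(
      params = gibrat_params(D = 1, L = exp(-0.5), I_peak = 1),
      init = NULL, horizon = 10, t0 = 1e-6))
}

#' Run a simulation from a preset or config
#'
#' @param config A preset name (see [epi_preset()]), a list as returned by
#'   [epi_preset()], or a config list parsed from JSON by [read_config()].
#' @param ... Passed to [simulate_epidemic()] (e.g. `n_out`, `rtol`).
#' @return An `epi_trajectory`.
#' @export
run_simulate <- function(config, ...) {
  if (is.character(config)) config <- epi_preset(config)
  stopifnot(is.list(config), !is.null(config$params),
            !is.null(config$horizon))
  simulate_epidemic(config$params, config$init, horizon = config$horizon,
                    t0 = config$t0, ...)
}

#' Transient, entropy and matching features of a curve
#'
#' One pipeline row per curve: peak/inflection times and values, cut times,
#' normalized entropy, and the log-normal reference matches.  Features that
#' cannot be computed (e.g. no interior maximum) are reported as `NA` with
#' a `reason` note; the run continues.
#'
#' @inheritParams shannon_entropy
#' @param k,eps Cut-time thresholds, see [cut_times()].
#' @param variant Reference-peak inversion variant, see [match_Drm()].
#' @return A one-row tibble with columns `D`, `L`, `I_D`, `I_L`, `tI1`,
#'   `tI2`, `tI3`, `S_In1`, `Drm`, `sigma_rm`, `sigma_rmv`, `var_In`,
#'   `variant`, `reason`.
#' @export
run_features <- function(x, eta = 1, k = c(1, 1, 1), eps = 0.01,
                         variant = c("printed", "sqrt_pi")) {
  variant <- match.arg(variant)
  feats <- transient_features(x)
  cuts <- cut_times(x, k = k, eps = eps)
  m <- tryCatch(match_reference(x, variant = variant),
                error = function(e) NULL)
  reason <- if (!feats$found_D) "no interior maximum"
            else if (is.null(m)) "matching failed"
            else NA_character_
  tibble::tibble(
    D = feats$D, L = feats$L, I_D = feats$I_D, I_L = feats$I_L,
    tI1 = cuts$tI1, tI2 = cuts$tI2, tI3 = cuts$tI3,
    S_In1 = if (is.null(m)) NA_real_ else m$S_In1,
    Drm = if (is.null(m)) NA_real_ else m$D_rm,
    sigma_rm = if (is.null(m)) NA_real_ else m$sigma_rm,
    sigma_rmv = if (is.null(m)) NA_real_ else m$sigma_rmv,
    var_In = if (is.null(m)) NA_real_ else m$var_In,
    variant = variant, reason = reason)
}

#' Sweep a parameter and collect features
#'
#' Re-runs a preset with one scalar knob varied over a grid and binds the
#' per-run feature rows.  The knob may address a rate (`"beta"`, `"gamma"`,
#' `"kV"`, `"kT"`) or an initial condition (`"S0"`, `"I0"`, `"R0"`).
#'
#' @param config Preset name or list, as in [run_simulate()].
#' @param var Name of the swept variable.
#' @param grid Numeric vector of values (nonempty).
#' @param ... Passed to [run_features()].
#' @param n_out Output grid size for each simulation.
#' @return A tibble with the swept value in column `value` plus the
#'   [run_features()] columns.
#' @export
sweep_features <- function(config, var, grid, ..., n_out = 2001L) {
  if (is.character(config)) config <- epi_preset(config)
  if (length(grid) == 0L) abort("sweep grid must be nonempty.")
  rate_names <- c("beta", "gamma", "kV", "kT")
  init_names <- c(S0 = "S", I0 = "I", R0 = "R")
  if (!var %in% c(rate_names, names(init_names)))
    abort(paste0("unknown sweep variable `", var, "`."))
  purrr::map_dfr(grid, function(v) {
    cfg <- config
    if (var %in% rate_names) {
      p <- unclass(cfg$params)
      p[[var]] <- v
      cfg$params <- if (inherits(config$params, "sir_params"))
        sir_params(p$beta, p$gamma)
      else sis_params(p$beta, p$gamma, p$kV, p$kT)
    } else {
      cfg$init[[init_names[[var]]]] <- v
    }
    traj <- run_simulate(cfg, n_out = n_out)
    dplyr::bind_cols(tibble::tibble(value = v), run_features(traj, ...))
  })
}
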