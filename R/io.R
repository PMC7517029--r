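# CSV and JSON interfaces.  Trajectory CSV has header t,S,I,R (missing
# compartments omitted), time in years, full float precision so the file
# round-trips exactly.

#' Write a trajectory to CSV
#'
#' @param traj An `epi_trajectory` (or any tibble with a `t` column and
#'   compartment columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  # 17 significant digits guarantee an exact double round trip
  cells <- vapply(df, function(x) sprintf("%.17g", x), character(nrow(df)))
  lines <- c(paste(names(df), collapse = ","),
             apply(cells, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory (or any time/infection curve) from CSV
#'
#' Accepts the `t,S,I,R` layout written by [write_trajectory()] as well as
#' plain two-column `time, infectious` files (the second column is taken as
#' `I` when no `I` column is named).
#'
#' @param path CSV file path.
#' @return A tibble with column `t` and the compartments present.
#' @export
read_trajectory <- function(path) {
  # base read.csv parses doubles with correctly-rounded strtod, so the
  # 17-digit representation written by write_trajectory() round-trips exactly
  df <- tibble::as_tibble(utils::read.csv(path))
  names(df)[1L] <- "t"
  if (!"I" %in% names(df) && ncol(df) == 2L) names(df)[2L] <- "I"
  if (!"I" %in% names(df)) abort("no infectious column found.")
  df
}

#' Turn a sampled curve into an `epi_curve`
#'
#' Builds a function-backed curve from tabulated `(t, I)` values by
#' monotone-grid spline interpolation; derivative accessors use the spline's
#' derivatives, which is adequate for feature detection on smooth curves
#' (supply analytic curves where oracle accuracy matters).
#'
#' @param df Tibble with columns `t` (strictly increasing, positive) and
#'   `I`.
#' @return An [epi_curve()].
#' @export
as_epi_curve <- function(df) {
  stopifnot(all(c("t", "I") %in% names(df)))
  t <- df$t; y <- df$I
  if (any(diff(t) <= 0)) abort("`t` must be strictly increasing.")
  if (t[1L] <= 0) abort("`t` must be positive.")
  sf <- stats::splinefun(t, y, method = "natural")
  epi_curve(function(x) sf(x), support = range(t),
            dI = function(x) sf(x, deriv = 1L),
            d2I = function(x) sf(x, deriv = 2L))
}

#' Read a JSON experiment config
#'
#' Accepts a JSON object with keys `model` (`"sir"`, `"sis"` or
#' `"gibrat"`), the rates `beta`, `gamma`, `kV`, `kT` (or `D`, `L`,
#' `I_peak` for the Gibrat model), the initial conditions `S0`, `I0`, `R0`,
#' and `t0`, `horizon`.
#'
#' @param path JSON file path.
#' @return A config list usable by [run_simulate()].
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- j$model %||% abort("config must name a `model`.")
  params <- switch(model,
    sir = sir_params(j$beta, j$gamma),
    sis = sis_params(j$beta, j$gamma, j$kV %||% 0, j$kT %||% 0),
    gibrat = gibrat_params(j$D %||% 1, j$L %||% ((j$D %||% 1) * exp(-0.5)),
                           j$I_peak %||% 1),
    abort(paste0("unknown model `", model, "`.")))
  init <- if (model == "gibrat") NULL else
    c(S = j$S0 %||% 0, I = j$I0 %||% 0, R = j$R0 %||% 0)
  list(params = params, init = init,
       horizon = j$horizon %||% abort("config must set `horizon`."),
       t0 = j$t0)
}
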