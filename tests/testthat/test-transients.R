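test_that("peak and inflection detection matches Gibrat closed forms", {
  # L(c) = exp(-(1 + sqrt(1 + 4c)) / (2c)) is the rising-branch inflection
  for (cc in c(2, 4, 6, 10)) {
    L_true <- exp(-(1 + sqrt(1 + 4 * cc)) / (2 * cc))
    fx <- fixture_curve("gibrat", list(D = 1, L = L_true))
    ft <- transient_features(fx)
    expect_true(ft$found_D && ft$found_L)
    expect_equal(ft$D, 1, tolerance = 1e-6)
    expect_equal(ft$L, L_true, tolerance = 1e-6)
    # root residuals are tiny relative to the derivative scale
    f <- curve_funs(fx)
    tt <- seq(f$support[1], f$support[2], length.out = 2001)
    expect_lt(abs(f$dI(ft$D)), 1e-8 * max(abs(f$dI(tt))))
    expect_lt(abs(f$d2I(ft$L)), 1e-8 * max(abs(f$d2I(tt))))
  }
})

test_that("detection on the integrated Gibrat trajectory agrees with the curve", {
  traj <- simulate_epidemic(gibrat6(), horizon = 10)
  ft <- transient_features(traj)
  expect_equal(ft$D, 1, tolerance = 1e-6)
  expect_equal(ft$L, exp(-0.5), tolerance = 1e-6)
  expect_equal(ft$I_D, 1, tolerance = 1e-6)
  expect_equal(ft$I_L, exp(-0.75), tolerance = 1e-6)
})

test_that("monotone curves report not-found rather than erroring", {
  traj <- run_simulate(epi_preset("sir_decay"), n_out = 2001L)
  expect_false(find_first_maximum(traj)$found)
  mono <- epi_curve(function(t) exp(-t), support = c(0.01, 5))
  expect_false(find_first_maximum(mono)$found)
  alt <- check_alternation(mono)
  expect_true(alt$alternates)          # vacuously: no zeros at all
  expect_length(alt$DS, 0)
})

test_that("a grazing zero of the first derivative declares no maximum", {
  # dI = -(t - 1)^2 * I touches zero at t = 1 without changing sign
  fx <- epi_curve(function(t) exp(-(t - 1)^3 / 3), support = c(0.2, 1.8),
                  dI = function(t) -(t - 1)^2 * exp(-(t - 1)^3 / 3))
  expect_false(find_first_maximum(fx)$found)
})

test_that("derivative zeros of an oscillatory curve strictly interleave", {
  fx <- fixture_curve("oscillatory", list(a = 1, omega = 2 * pi))
  alt <- check_alternation(fx)
  expect_true(alt$alternates)
  expect_gte(length(alt$DS), 3)
  # extrema of I sit exactly at the zeros of cos(omega t)
  expected_DS <- (2 * (0:5) + 1) / 4
  expect_equal(alt$DS, expected_DS, tolerance = 1e-8)
  expect_lt(alt$LS[1], alt$DS[1])     # first inflection precedes first extremum
})

test_that("cut times bound settling and respond monotonically to eps", {
  traj <- run_simulate(epi_preset("sir_decay"), n_out = 2001L)
  p <- attr(traj, "params")
  I0 <- 0.5
  k1 <- 1; eps <- 0.01
  ct <- cut_times(traj, k = c(k1, 1, 1), eps = eps)
  lower <- (log(I0) - log(k1) + abs(log(eps))) / p$gamma
  expect_gte(ct$tI1, lower)
  expect_true(all(is.finite(c(ct$tI1, ct$tI2, ct$tI3))))
  # shrinking eps can only postpone the cut
  prev <- -Inf
  for (e in c(0.05, 0.02, 0.01, 0.005)) {
    ti <- cut_times(traj, eps = e)$tI1
    expect_gte(ti, prev)
    prev <- ti
  }
  # a curve already below threshold cuts at the start of the support
  tiny <- epi_curve(function(t) rep(1e-6, length(t)), support = c(0.1, 2),
                    dI = function(t) rep(0, length(t)),
                    d2I = function(t) rep(0, length(t)))
  ct0 <- cut_times(tiny, eps = 0.01)
  expect_equal(ct0$tI1, 0.1)
  expect_error(cut_times(traj, eps = 2))
  expect_error(cut_times(traj, k = c(0.5, 1, 1)))
})

test_that("SIS peak preconditions predict the interior maximum", {
  p <- sis_params(beta = 30, gamma = 50, kV = 1, kT = 50)
  expect_equal(sis_peak_preconditions(p, c(S = 10, I = 0.2))$S_threshold,
               100 / 30)
  pre <- epi_preset("sis_demo")
  pc <- sis_peak_preconditions(pre$params, pre$init)
  expect_true(pc$all_hold)
  traj <- run_simulate(pre, n_out = 2001L)
  mx <- find_first_maximum(traj)
  expect_true(mx$found)
  # the maximum is reached where S crosses (gamma + kT)/beta
  expect_equal(curve_funs(traj)$S(mx$D), pc$S_threshold, tolerance = 1e-6)

  # starting exactly at the threshold: dI0 = 0 and no interior maximum
  pre0 <- epi_preset("sis_no_peak")
  pc0 <- sis_peak_preconditions(pre0$params, pre0$init)
  expect_false(pc0$cond1)
  expect_equal(pc0$dI0, 0)
  traj0 <- run_simulate(pre0, n_out = 2001L)
  expect_false(find_first_maximum(traj0)$found)
})
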