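test_that("reference peak time inversion is exact for both variants", {
  # printed inversion: S = ln(pi) + ln(D) + 1
  expect_equal(match_Drm(1 + log(pi)), 1)
  expect_equal(match_Drm(1), 1 / pi)
  for (D in c(0.25, 1, 3)) {
    expect_equal(match_Drm(log(pi) + log(D) + 1, "printed"), D)
    expect_equal(match_Drm(0.5 * log(pi) + log(D) + 1, "sqrt_pi"), D)
  }
})

test_that("entropy-matching width recovers the generating width", {
  for (par in list(c(1, 0.3), c(0.5, 0.45), c(2, 0.7))) {
    D <- par[1]; s0 <- par[2]
    S <- normalized_entropy(function(t) lognormal_pdf(D, s0, t))$value
    expect_equal(match_sigma_rm(S, D), s0, tolerance = 1e-6)
  }
  # Gibrat with c = 6 is the log-normal with sigma = 1/sqrt(6)
  S6 <- normalized_entropy(gibrat6_curve())$value
  expect_equal(match_sigma_rm(S6, 1), 1 / sqrt(6), tolerance = 1e-6)
  # monotone inversion
  sig <- vapply(c(0.5, 0.7, 0.9), function(S) match_sigma_rm(S, 1),
                numeric(1))
  expect_true(all(diff(sig) > 0))
  expect_error(match_sigma_rm(-50, 1))
})

test_that("curve variance matches the closed-form log-normal moments", {
  v <- curve_variance(function(t) lognormal_pdf(1, 1 / sqrt(6), t))
  expect_equal(v, lognormal_variance(1, 1 / sqrt(6)), tolerance = 1e-8)
  expect_equal(v, (exp(1 / 6) - 1) * exp(0.5), tolerance = 1e-8)
  # narrow densities concentrate: variance goes to zero with the width
  expect_lt(curve_variance(function(t) lognormal_pdf(1, 0.01, t)), 2e-4)
  # a shifted unit-mass bump keeps its central second moment
  bump <- function(m) function(t) exp(-(t - m)^2 / 0.02) / sqrt(0.02 * pi)
  v1 <- curve_variance(bump(2), support = c(1, 3))
  v2 <- curve_variance(bump(5), support = c(4, 6))
  expect_equal(v1, v2, tolerance = 1e-8)
  # off-mass curves are renormalized with a warning
  expect_warning(curve_variance(function(t) 2 * lognormal_pdf(1, 0.3, t)))
})

test_that("variance-matching width recovers the generating width", {
  for (par in list(c(1, 0.3), c(0.5, 0.45), c(2, 0.7))) {
    D <- par[1]; s0 <- par[2]
    v <- curve_variance(function(t) lognormal_pdf(D, s0, t))
    expect_equal(match_sigma_rmv(v, D), s0, tolerance = 1e-6)
  }
  expect_equal(match_sigma_rmv(0.29901, 1), 0.40825, tolerance = 1e-4)
  expect_error(match_sigma_rmv(-1, 1))
})

test_that("the full matching pipeline is self-consistent on the reference family", {
  fx <- fixture_curve("lognormal", list(Dr = 1.5, sigma = 0.35))
  m <- match_reference(fx)
  expect_equal(m$D, 1.5, tolerance = 1e-6)
  expect_equal(m$sigma_rm, 0.35, tolerance = 1e-6)
  expect_equal(m$sigma_rmv, 0.35, tolerance = 1e-6)
  td <- tidy(m)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$variant, "printed")
  m2 <- match_reference(fx, variant = "sqrt_pi")
  expect_equal(m2$D_rm / m$D_rm, sqrt(pi), tolerance = 1e-12)
})

test_that("Gibrat pipeline numbers chain through the printed inversion", {
  m <- match_reference(gibrat6_curve())
  expect_equal(m$S_In1, 0.68973, tolerance = 1e-4)
  expect_equal(m$D_rm, exp(m$S_In1 - 1) / pi)
  expect_equal(m$D_rm, 0.23340, tolerance = 1e-3)
})

test_that("multi-compartment curves drift from the fixed reference width as S0/I0 grows", {
  # the entropy/variance-matched widths depart from sigma_r = 1/sqrt(2)
  # increasingly as the initial susceptible-to-infectious ratio grows
  pre <- epi_preset("sir_epidemic")
  gaps <- vapply(c(0.3, 0.6, 0.99), function(S0) {
    cfg <- pre
    cfg$init["S"] <- S0
    cfg$init["R"] <- 1 - S0 - 0.01
    traj <- run_simulate(cfg, n_out = 2001L)
    m <- match_reference(traj)
    abs(m$sigma_rmv - 1 / sqrt(2))
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})
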