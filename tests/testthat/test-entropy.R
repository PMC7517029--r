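test_that("entropy quadrature matches the log-normal closed form", {
  for (s in seq(0.2, 1, length.out = 5)) {
    for (Dr in c(0.5, 1, 2)) {
      se <- shannon_entropy(function(t) lognormal_pdf(Dr, s, t), eta = 1)
      mu <- log(Dr) + s^2
      expect_equal(se$value, mu + 0.5 + log(s * sqrt(2 * pi)),
                   tolerance = 1e-8)
      expect_lt(se$quad_error_estimate, 1e-8 * (1 + abs(se$value)))
    }
  }
})

test_that("uniform density entropy is log of the interval length", {
  for (ab in list(c(1, 3), c(0.5, 4))) {
    a <- ab[1]; b <- ab[2]
    u <- function(t) ifelse(t >= a & t <= b, 1 / (b - a), 0)
    se <- shannon_entropy(u, eta = 1, support = c(a, b))
    expect_equal(se$value, log(b - a), tolerance = 1e-8)
  }
})

test_that("entropy value is stable under quadrature refinement", {
  f <- function(t) lognormal_pdf(1, 0.4, t)
  v1 <- shannon_entropy(f, rel_tol = 1e-9)$value
  v2 <- shannon_entropy(f, rel_tol = 1e-10)$value
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("normalized Gibrat entropy equals the log-normal entropy", {
  fx <- gibrat6_curve()
  ne <- normalized_entropy(fx, eta = 1)
  expect_equal(ne$value, 1 / 6 + 0.5 + log(sqrt(2 * pi / 6)),
               tolerance = 1e-6)
  # scale invariance
  big <- fixture_curve("gibrat", list(D = 1, L = exp(-0.5), I_peak = 137))
  expect_equal(normalized_entropy(big)$value, ne$value, tolerance = 1e-9)
  # time rescaling t -> a t shifts the order-1 value by +log(a)
  a <- 2.5
  scaled <- fixture_curve("gibrat", list(D = a, L = a * exp(-0.5)))
  expect_equal(normalized_entropy(scaled)$value, ne$value + log(a),
               tolerance = 1e-6)
})

test_that("entropy rejects non-integrable curves", {
  expect_error(shannon_entropy(function(t) 1 / t))
  expect_error(normalized_entropy(function(t) rep(0, length(t)),
                                  support = c(1, 2)))
})

test_that("truncated entropy inflects at the infection maximum", {
  fx <- gibrat6_curve()
  f <- curve_funs(fx)
  expect_equal(truncated_entropy(fx, 1e-6), 0, tolerance = 1e-8)
  # analytic second derivative -dI(t)(1 + ln I(t)) vanishes at D = 1
  D <- find_first_maximum(fx)$D
  expect_equal(-f$dI(D) * (1 + log(f$I(D))), 0, tolerance = 1e-8)
  # and the finite-difference curvature of the running entropy changes
  # sign there
  g <- function(t) truncated_entropy(fx, t)
  h <- 2e-3
  curv <- function(t) (g(t + h) - 2 * g(t) + g(t - h)) / h^2
  tt <- seq(0.9, 1.1, by = 0.02)
  v <- vapply(tt, curv, numeric(1))
  j <- which(v[-1] * v[-length(v)] < 0)[1]
  root <- uniroot(curv, c(tt[j], tt[j + 1]), tol = 1e-8)$root
  expect_equal(root, D, tolerance = 1e-3)
  # monotone growth while I stays inside (0, 1/e): -I ln I > 0 there
  small <- epi_curve(function(t) rep(0.1, length(t)), support = c(0.5, 2),
                     dI = function(t) rep(0, length(t)),
                     d2I = function(t) rep(0, length(t)))
  vals <- truncated_entropy(small, c(0.8, 1.2, 1.6, 2))
  expect_true(all(diff(vals) > 0))
})

test_that("delta kernel behaves as its expansion predicts", {
  base <- fixture_curve("lognormal")
  f <- curve_funs(base)
  tt <- c(0.5, 1, 2)
  # identical curves give delta = 0 for any eta
  expect_equal(delta_error(f$I, f$I, eta = 1, tt), rep(0, 3))
  expect_equal(delta_error(f$I, f$I, eta = 3, tt), rep(0, 3))
  # at eta = 1 the kernel is independent of t's explicit factor
  I2 <- function(t) f$I(t) * 1.001
  d1 <- delta_error(I2, f$I, eta = 1, tt)
  expo <- I2(tt) * log(I2(tt)) - f$I(tt) * log(f$I(tt))
  expect_equal(d1, expm1(expo), tolerance = 1e-12)
  # first-order response to a small multiplicative perturbation
  eps <- 1e-6
  Ieps <- function(t) f$I(t) * (1 + eps)
  d <- delta_error(Ieps, f$I, eta = 1, tt)
  lin <- eps * f$I(tt) * (1 + log(f$I(tt)))
  expect_equal(d, lin, tolerance = 1e-4)
})

test_that("entropy error decomposes into linear plus higher-order parts", {
  base <- fixture_curve("lognormal")
  for (amp in c(1e-3, 0.05, 0.3)) {
    pert <- fixture_curve("perturbed", list(base = base, amplitude = amp),
                          seed = 42)
    ee <- entropy_error(pert, base, eta = 1)
    expect_true(ee$series_converged)
    expect_lt(ee$max_abs_delta, 0.9)
    expect_lt(abs(ee$S_tilde - (ee$S_tilde_L + ee$S_tilde_hh)),
              1e-6 * (1 + abs(ee$S_tilde)))
  }
  # identical curves: all components vanish
  ee0 <- entropy_error(base, base)
  expect_equal(ee0$S_tilde, 0, tolerance = 1e-14)
  expect_equal(ee0$S_tilde_L, 0, tolerance = 1e-14)
  expect_equal(ee0$S_tilde_hh, 0, tolerance = 1e-14)
})

test_that("model-vs-reference entropy error is finite when the curves settle together", {
  # work in peak-rescaled time s = t/D so both densities are O(1) and the
  # error kernel stays inside its convergence disc
  traj <- run_simulate(epi_preset("sir_epidemic"), n_out = 2001L)
  f <- curve_funs(traj)
  D <- find_first_maximum(traj)$D
  mass <- integrate(f$I, f$support[1], f$support[2], rel.tol = 1e-10,
                    abs.tol = 0, subdivisions = 500L)$value
  In_s <- function(s) D * f$I(s * D) / mass        # unit mass in s
  ref <- function(s) lognormal_pdf(1, 1 / sqrt(2), s)
  sup <- c(1e-3, f$support[2] / D)
  ee <- entropy_error(In_s, ref, eta = 1, support = sup)
  expect_true(is.finite(ee$S_tilde))
  expect_true(ee$series_converged)
  # both curves decay, so the pointwise discrepancy dies at the horizon
  expect_lt(abs(delta_error(In_s, ref, 1, sup[2])), 1e-3)
})
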