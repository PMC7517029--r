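test_that("maximum-dissipation width follows 1/sqrt(2 eta)", {
  expect_equal(round(sigma_max_dissipation(3), 3), 0.408)
  expect_equal(sigma_max_dissipation(3), 1 / sqrt(6))
  expect_equal(sigma_max_dissipation(0.5), 1)
  expect_equal(sigma_max_dissipation(1), 1 / sqrt(2))
  expect_error(sigma_max_dissipation(0))
})

test_that("reference geometry at eta = 3 reproduces the classical triple", {
  ref <- lognormal_ref(Dr = 1, eta = 3)
  mi <- mode_and_inflection(ref)
  expect_equal(mi$Dr, 1)
  expect_equal(mi$Dr / mi$Lr, exp(0.5), tolerance = 1e-12)
  expect_equal(round(mi$Dr / mi$Lr, 3), 1.649)
  r <- peak_to_inflection_ratio(ref)
  expect_equal(r, exp(0.75), tolerance = 1e-12)
  # the historically quoted 2.120 agrees with the analytic value to 0.15%
  expect_lt(abs(r - 2.120) / 2.120, 0.0015)
  # self-consistency with direct curve evaluation
  expect_equal(r, reference_curve(ref, mi$Dr) / reference_curve(ref, mi$Lr),
               tolerance = 1e-10)
})

test_that("the inflection quadratic matches a brute-force curvature scan", {
  skip_if_not_installed("numDeriv")
  for (sigma in c(0.2, sigma_max_dissipation(3), 0.7, 1.0)) {
    ref <- lognormal_ref(Dr = 1, sigma = sigma)
    mi <- mode_and_inflection(ref)
    d2 <- function(t)
      numDeriv::hessian(function(x) reference_curve(ref, x), t)[1, 1]
    # bracket the rising-branch curvature sign change independently
    tt <- seq(mi$Dr / 20, mi$Dr * 0.999, length.out = 400)
    v <- vapply(tt, d2, numeric(1))
    j <- which(v[-1] * v[-length(v)] < 0)
    j <- j[length(j)]                  # last sign change before the mode
    L_scan <- uniroot(d2, c(tt[j], tt[j + 1]), tol = 1e-12)$root
    expect_equal(L_scan, mi$Lr, tolerance = 1e-8)
    expect_lt(mi$Lr, mi$Dr)
  }
})

test_that("reference curve peaks at Dr and vanishes at the tails", {
  ref <- lognormal_ref(Dr = 2, sigma = 0.5, I0 = 3)
  opt <- optimize(function(t) reference_curve(ref, t), c(0.01, 20),
                  maximum = TRUE, tol = 1e-10)
  expect_equal(opt$maximum, 2, tolerance = 1e-6)
  expect_lt(reference_curve(ref, 1e-8), 1e-30)
  expect_lt(reference_curve(ref, 1e6), 1e-30)
  expect_error(reference_curve(ref, 0))
})

test_that("reference curve is proportional to the normalized Gibrat curve", {
  # sigma^2 = 1/c, mu = ln D + sigma^2: identical shapes, ratio = mass factor
  gp <- gibrat6()
  ref <- lognormal_ref(Dr = 1, sigma = 1 / sqrt(6))
  tt <- exp(seq(-3, 3, length.out = 201))
  ratio <- infection_closed_form(gp, tt) / reference_curve(ref, tt)
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-8)
  pdf_ratio <- infection_closed_form(gp, tt) / lognormal_pdf(1, 1 / sqrt(6), tt)
  expect_lt(diff(range(pdf_ratio)) / mean(pdf_ratio), 1e-8)
})

test_that("mode-parameterized log-normal density has unit mass and known moments", {
  for (par in list(c(1, 1 / sqrt(6)), c(0.5, 0.3), c(2, 0.8))) {
    Dr <- par[1]; s <- par[2]
    mass <- integrate(function(t) lognormal_pdf(Dr, s, t), 0, Inf,
                      rel.tol = 1e-12)$value
    expect_equal(mass, 1, tolerance = 1e-10)
    mu <- log(Dr) + s^2
    mean_q <- integrate(function(t) t * lognormal_pdf(Dr, s, t), 0, Inf,
                        rel.tol = 1e-12)$value
    expect_equal(mean_q, exp(mu + s^2 / 2), tolerance = 1e-9)
    opt <- optimize(function(t) lognormal_pdf(Dr, s, t),
                    c(Dr / 10, Dr * 10), maximum = TRUE, tol = 1e-10)
    expect_equal(opt$maximum, Dr, tolerance = 1e-6)
  }
})

test_that("closed-form variance matches quadrature and grows with sigma", {
  v <- lognormal_variance(1, 1 / sqrt(6))
  vq <- integrate(function(t) {
    m <- exp(log(1) + 1 / 6 + 1 / 12)
    (t - m)^2 * lognormal_pdf(1, 1 / sqrt(6), t)
  }, 0, Inf, rel.tol = 1e-12)$value
  expect_equal(v, (exp(1 / 6) - 1) * exp(0.5), tolerance = 1e-12)
  expect_equal(v, vq, tolerance = 1e-8)
  sig <- seq(0.05, 1.5, length.out = 40)
  expect_true(all(diff(lognormal_variance(1, sig)) > 0))
  expect_lt(lognormal_variance(1, 1e-4), 1e-7)
})

test_that("closed-form entropy equals the differential entropy by quadrature", {
  for (s in seq(0.2, 1, length.out = 5)) {
    for (Dr in c(0.5, 1, 2)) {
      cf <- reference_entropy_closed(s, Dr, 1)
      q <- integrate(function(t) {
        p <- lognormal_pdf(Dr, s, t)
        ifelse(p > 0, -p * log(p), 0)
      }, 0, Inf, rel.tol = 1e-12)$value
      expect_equal(cf, q, tolerance = 1e-8)
    }
  }
  expect_equal(reference_entropy_closed(1 / sqrt(6), 1, 1),
               1 / 6 + 1 / 2 + log(sqrt(2 * pi / 6)), tolerance = 1e-12)
  expect_equal(reference_entropy_closed(1 / sqrt(2), 1, 1),
               0.5 * log(pi) + 1, tolerance = 1e-12)
  # strictly increasing in sigma
  ss <- seq(0.05, 2, length.out = 50)
  expect_true(all(diff(reference_entropy_closed(ss, 1, 1)) > 0))
  expect_true(all(diff(reference_entropy_closed(ss, 1, 3)) > 0))
})
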