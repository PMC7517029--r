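# shared fixtures, built in code

gibrat6 <- function() gibrat_params(D = 1, L = exp(-0.5), I_peak = 1)

gibrat6_curve <- function() fixture_curve("gibrat", list(D = 1, L = exp(-0.5)))

# independent finite-difference derivatives for oracle checks
fd1 <- function(f, t, h = 1e-6 * max(abs(t), 1)) (f(t + h) - f(t - h)) / (2 * h)
fd2 <- function(f, t, h = 1e-4 * max(abs(t), 1))
  (f(t + h) - 2 * f(t) + f(t - h)) / h^2
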