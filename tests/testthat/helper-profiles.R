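# Build a profile whose per-position means lie exactly on a model curve
# (no noise, no detection floor) -- the self-consistency fixture.
exact_profile <- function(params, L = 8, family = "ti_gompertz", step = 0.5,
                          n_rep = 1, basal_exclusion = 1) {
  x <- seq(0, L, by = step)
  y <- growth_curve(family, params, x)
  root_profile(L, x, matrix(rep(y, n_rep), ncol = n_rep),
               basal_exclusion_cm = basal_exclusion)
}

# Noisy profile from a model curve with replicate-level Gaussian noise.
noisy_profile <- function(params, L = 8, family = "ti_gompertz", step = 0.5,
                          n_rep = 12, sd = 1, seed = 1, basal_exclusion = 1) {
  set.seed(seed)
  x <- seq(0, L, by = step)
  y <- growth_curve(family, params, x)
  vals <- pmin(pmax(y + matrix(rnorm(length(x) * n_rep, sd = sd),
                               nrow = length(x)), 0), 100)
  root_profile(L, x, vals, basal_exclusion_cm = basal_exclusion)
}

# fixed-grid composite Simpson rule: the independent quadrature oracle
simpson_oracle <- function(f, a, b, n = 10000L) {
  x <- seq(a, b, length.out = n + 1L)
  y <- f(x)
  h <- (b - a) / n
  h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, 2)]) + 2 * sum(y[seq(3, n - 1, 2)]))
}

PAR8 <- c(A = 33.34, B = 0.751, C = 2.824)   # unified parameters at L = 8
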