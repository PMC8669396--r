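test_that("a noiseless profile is an exact fixed point of the fit", {
  pr <- exact_profile(PAR8, L = 8)
  fit <- fit_profile(pr, "ti_gompertz")
  expect_true(fit$converged)
  expect_equal(unname(fit$params), unname(PAR8), tolerance = 1e-4)
  expect_lt(fit$SSR, 1e-10)
  expect_gte(fit$R2, 1 - 1e-10)
})

test_that("W0 and Ti fits of the same profile give identical curves", {
  pr <- exact_profile(PAR8, L = 8)
  fit_ti <- fit_profile(pr, "ti_gompertz")
  fit_w0 <- fit_profile(pr, "w0_gompertz")
  x <- seq(0, 8, length.out = 500)
  expect_lt(max(abs(predict(fit_ti, x) - predict(fit_w0, x))), 1e-6)
  # converting the w0 estimate lands on the ti estimate
  conv <- gompertz_convert(coef(fit_w0), "w0_gompertz", "ti_gompertz")
  expect_equal(unname(conv), unname(coef(fit_ti)), tolerance = 1e-4)
})

test_that("noisy replicated profiles are fitted with R2 > 0.99", {
  for (seed in 1:10) {
    pr <- noisy_profile(PAR8, L = 8, n_rep = 12, sd = 1, seed = seed)
    fit <- fit_profile(pr, "ti_gompertz")
    expect_true(fit$converged)
    expect_gt(fit$R2, 0.99)
  }
})

test_that("parameters are recovered across the design space", {
  # median relative error over simulated profiles below 5%
  set.seed(99)
  errs <- replicate(40, {
    truth <- c(A = runif(1, 20, 45), B = runif(1, 0.5, 2),
               C = runif(1, 2, 3.2))
    pr <- noisy_profile(truth, L = 12, n_rep = 12, sd = 1,
                        seed = sample.int(1e6, 1))
    fit <- suppressWarnings(fit_profile(pr, "ti_gompertz"))
    abs(coef(fit) - truth) / truth
  })
  expect_lt(max(apply(errs, 1, median)), 0.05)
})

test_that("fit uses per-position means and ignores replicate order", {
  pr <- noisy_profile(PAR8, L = 8, n_rep = 12, sd = 1, seed = 5)
  shuffled <- pr
  set.seed(1)
  for (i in seq_along(shuffled$positions)) {
    shuffled$values[i, ] <- sample(shuffled$values[i, ])
  }
  expect_equal(coef(fit_profile(pr)), coef(fit_profile(shuffled)))
})

test_that("degenerate profiles are rejected", {
  zeros <- root_profile(3, seq(0, 3, 0.5), matrix(0, 7, 2))
  expect_error(default_start(zeros), "no aerenchyma signal")
  expect_error(fit_profile(zeros), "no aerenchyma signal")
  short <- root_profile(2, c(0, 0.5, 1), matrix(1:3, ncol = 1),
                        basal_exclusion_cm = 0)
  expect_error(fit_profile(short), "too few")
})

test_that("default starting values are in bounds and lead to convergence", {
  for (seed in 1:10) {
    pr <- noisy_profile(PAR8, L = 10, n_rep = 12, sd = 1, seed = seed)
    for (fam in growth_families()) {
      st <- default_start(pr, fam)
      expect_true(all(is.finite(st)))
      expect_true(st[["A"]] > 0 && st[["B"]] >= 0.05 && st[["B"]] <= 10)
      fit <- suppressWarnings(fit_profile(pr, fam))
      expect_true(fit$converged)
    }
  }
  # A0 is 1.05 times the maximum mean
  pr <- exact_profile(c(A = 40, B = 0.751, C = 2.824), L = 16)
  st <- default_start(pr, "ti_gompertz")
  expect_equal(st[["A"]], 1.05 * max(profile_means(pr)$mean))
})

test_that("information criteria follow the least-squares forms", {
  ic <- information_criteria(15, 3, 15)
  expect_equal(ic[["AIC"]], 6)
  expect_equal(ic[["BIC"]], 3 * log(15))
  # frozen from hand arithmetic: 20*ln(0.1) + 6
  expect_equal(information_criteria(20, 3, 2)[["AIC"]], -40.051701859880914)
  # doubling SSR raises both criteria by n*ln(2)
  ic2 <- information_criteria(15, 3, 30)
  expect_equal(ic2 - ic, c(AIC = 15 * log(2), BIC = 15 * log(2)))
  # printed AIC variant
  expect_equal(information_criteria(15, 3, 15, variant = "printed")[["AIC"]],
               15 + 0 + 6)
  expect_warning(ic0 <- information_criteria(10, 3, 0), "zero")
  expect_equal(unname(ic0), c(-Inf, -Inf))
})

test_that("every fit satisfies the AIC/BIC relationship", {
  pr <- noisy_profile(PAR8, L = 10, n_rep = 12, sd = 1, seed = 2)
  for (fam in growth_families()) {
    fit <- suppressWarnings(fit_profile(pr, fam))
    expect_equal(fit$AIC - fit$BIC, fit$p * (2 - log(fit$n)))
    expect_gte(fit$SSR, 0)
    expect_true(fit$R2 >= 0 && fit$R2 <= 1)
  }
})

test_that("model comparison ranks the generating family first", {
  # truth = Ti-Gompertz: a Gompertz form wins by AIC in most seeds
  wins <- vapply(1:20, function(seed) {
    pr <- noisy_profile(PAR8, L = 10, n_rep = 12, sd = 1, seed = seed)
    tab <- compare_models(pr)
    tab$family[1] %in% c("ti_gompertz", "w0_gompertz")
  }, logical(1))
  expect_gt(mean(wins), 0.5)
  # truth = logistic: the logistic wins in most seeds
  wins_log <- vapply(1:20, function(seed) {
    pr <- noisy_profile(c(A = 35, B = 1.3, C = 4), L = 10,
                        family = "logistic", n_rep = 12, sd = 1, seed = seed)
    compare_models(pr)$family[1] == "logistic"
  }, logical(1))
  expect_gt(mean(wins_log), 0.5)
})

test_that("model comparison table is complete and ordered", {
  pr <- noisy_profile(PAR8, L = 8, n_rep = 12, sd = 1, seed = 3)
  tab <- compare_models(pr)
  expect_setequal(tab$family, growth_families())
  conv <- tab[tab$converged, ]
  expect_true(!is.unsorted(conv$AIC))
  expect_equal(conv$rank, seq_len(nrow(conv)))
})
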