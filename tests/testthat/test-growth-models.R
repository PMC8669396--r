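test_that("model families evaluate to their closed forms", {
  # at x = C the inner exponent of the Ti form is 1: value = A/e
  expect_equal(growth_curve("ti_gompertz", c(A = 44.8, B = 1, C = 2), 2),
               44.8 / exp(1))
  # asymptote at large x
  expect_equal(growth_curve("ti_gompertz", c(A = 44.8, B = 1, C = 2), 1e6),
               44.8)
  # logistic midpoint
  expect_equal(growth_curve("logistic", c(A = 10, B = 1, C = 0), 0), 5)
  # frozen from an independent high-precision evaluation of the formula
  expect_equal(growth_curve("ti_gompertz", PAR8, 1.0),
               0.65187643142425120, tolerance = 1e-12)
})

test_that("invalid inputs are rejected", {
  expect_error(growth_curve("richards", c(A = 1, B = 1, C = 1), 0),
               "unknown model family")
  expect_error(growth_curve("ti_gompertz", c(A = 1, B = NA, C = 1), 0),
               "non-finite")
  expect_error(growth_curve("ti_gompertz", c(A = 1, B = 1, C = 1), Inf),
               "finite")
  expect_error(growth_deriv("ti_gompertz", PAR8, 1, order = 4), "order")
})

test_that("Ti-Gompertz curve is increasing and bounded in (0, A)", {
  for (pars in list(PAR8, c(A = 10, B = 2, C = 1), c(A = 44.8, B = 0.3, C = 4))) {
    x <- seq(0, 16, by = 0.05)
    y <- growth_curve("ti_gompertz", pars, x)
    expect_true(all(diff(y) > 0))
    expect_true(all(y > 0 & y < pars[["A"]]))
  }
})

test_that("analytic derivatives match central differences", {
  h <- 1e-5
  x <- seq(0, 16, by = 0.5)
  for (fam in growth_families()) {
    pars <- switch(fam,
      ti_gompertz = PAR8,
      w0_gompertz = gompertz_convert(PAR8, "ti_gompertz", "w0_gompertz"),
      logistic = c(A = 30, B = 1.2, C = 4),
      von_bertalanffy = c(A = 35, B = 0.5, C = 0.9))
    num1 <- (growth_curve(fam, pars, x + h) - growth_curve(fam, pars, x - h)) / (2 * h)
    expect_equal(growth_deriv(fam, pars, x, 1), num1, tolerance = 1e-5)
    num2 <- (growth_deriv(fam, pars, x + h, 1) - growth_deriv(fam, pars, x - h, 1)) / (2 * h)
    expect_equal(growth_deriv(fam, pars, x, 2), num2, tolerance = 1e-5)
  }
  # third derivative of the Ti form, analytic vs differenced analytic second
  num3 <- (growth_deriv("ti_gompertz", PAR8, x + h, 2) -
             growth_deriv("ti_gompertz", PAR8, x - h, 2)) / (2 * h)
  expect_equal(growth_deriv("ti_gompertz", PAR8, x, 3), num3, tolerance = 1e-5)
})

test_that("Ti-Gompertz derivatives vanish at the critical abscissae", {
  A <- 44.8; B <- 1.0; C <- 2.0
  p <- c(A = A, B = B, C = C)
  expect_equal(growth_deriv("ti_gompertz", p, C, 1), A * B / exp(1))
  expect_equal(growth_deriv("ti_gompertz", p, C, 2), 0)
  x_map <- C - log(2.618) / B
  expect_lt(abs(growth_deriv("ti_gompertz", p, x_map, 3)), 1e-2)
  # exact root constant (3 + sqrt(5))/2 gives machine-precision zero
  x_map_exact <- C - log((3 + sqrt(5)) / 2) / B
  expect_lt(abs(growth_deriv("ti_gompertz", p, x_map_exact, 3)), 1e-8)
})

test_that("Gompertz reparameterization is exact and curve-preserving", {
  expect_equal(gompertz_convert(c(A = 10, B = 1, C = exp(1)),
                                "w0_gompertz", "ti_gompertz"),
               c(A = 10, B = 1, C = 1))
  # round trip is the identity
  rt <- gompertz_convert(gompertz_convert(PAR8, "ti_gompertz", "w0_gompertz"),
                         "w0_gompertz", "ti_gompertz")
  expect_equal(rt, PAR8, tolerance = 1e-12)
  # the two forms coincide pointwise
  w0 <- gompertz_convert(PAR8, "ti_gompertz", "w0_gompertz")
  x <- seq(0, 16, length.out = 2000)
  expect_lt(max(abs(growth_curve("ti_gompertz", PAR8, x) -
                      growth_curve("w0_gompertz", w0, x))), 1e-10)
  expect_error(gompertz_convert(PAR8, "ti_gompertz", "logistic"),
               "Gompertz")
  expect_error(gompertz_convert(c(A = 1, B = 1, C = -1),
                                "w0_gompertz", "ti_gompertz"), "positive")
})

test_that("definite integral matches the Simpson oracle and its limits", {
  expect_equal(growth_integral("ti_gompertz", PAR8, 3, 3), 0)
  expect_error(growth_integral("ti_gompertz", PAR8, 5, 3), "exceeds")
  # saturated plateau: ~ A * (x1 - x0)
  p_sat <- c(A = 20, B = 30, C = 0.1)
  expect_equal(growth_integral("ti_gompertz", p_sat, 10, 14), 20 * 4,
               tolerance = 1e-6)
  # frozen from an independent high-precision quadrature of the same formula
  p16 <- c(A = 44.8, B = 1.156, C = 2.206)
  expect_equal(growth_integral("ti_gompertz", p16, 0, 16),
               595.60159326564869, tolerance = 1e-8)
  # and against the in-suite Simpson oracle for a second family
  f <- function(x) growth_curve("logistic", c(A = 30, B = 1.2, C = 4), x)
  expect_equal(growth_integral("logistic", c(A = 30, B = 1.2, C = 4), 0, 16),
               simpson_oracle(f, 0, 16), tolerance = 1e-6)
})
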