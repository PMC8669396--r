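test_that("closed-form critical points reproduce the published 8-cm root", {
  cp <- critical_points(c(A = 33.34, B = 0.751, C = 2.824), root_length = 8)
  published <- c(InP = 1.14, MAP = 1.52, IP = 2.81, MDP = 4.10, MVP95 = 6.78)
  expect_true(all(abs(cp$points - published) <= 0.05))
  expect_false(any(cp$censored))
})

test_that("short roots censor the points beyond the observable segment", {
  cp4 <- critical_points(c(A = 23.18, B = 0.751, C = 3.012), root_length = 4)
  expect_true(is.na(cp4$points[["MDP"]]))
  expect_true(is.na(cp4$points[["MVP95"]]))
  # the inflection point equals the fitted parameter C and is always reported
  expect_equal(cp4$points[["IP"]], 3.012)
  expect_true(all(abs(cp4$points[c("InP", "MAP")] - c(1.53, 1.76)) <= 0.05))
})

test_that("ordering and symmetry invariants hold when all points exist", {
  for (B in c(0.3, 0.751, 2)) {
    p <- c(A = 40, B = B, C = 3)
    cp <- critical_points(p)$points
    expect_true(all(diff(cp[c("InP", "MAP", "IP", "MDP", "MVP95")]) > 0))
    # MAP and MDP are symmetric about C
    expect_equal(cp[["IP"]] - cp[["MAP"]], cp[["MDP"]] - cp[["IP"]])
    expect_equal(cp[["IP"]] - cp[["MAP"]], log((3 + sqrt(5)) / 2) / B)
    # curve values at the critical points are fixed fractions of A
    y <- growth_curve("ti_gompertz", p, cp)
    expect_equal(y[["IP"]], 40 / exp(1))
    expect_equal(y[["MAP"]] / 40, exp(-(3 + sqrt(5)) / 2))
    expect_equal(y[["MDP"]] / 40, exp(-(3 - sqrt(5)) / 2))
    expect_equal(y[["MVP95"]] / 40, 0.95)
    expect_equal(y[["InP"]], 1)
  }
})

test_that("numeric derivative roots agree with the closed forms", {
  expect_equal(derivative_roots(PAR8, order = 2), PAR8[["C"]],
               tolerance = 1e-8)
  r3 <- derivative_roots(c(A = 30, B = 0.751, C = 2.824), order = 3)
  expect_length(r3, 2)
  expect_equal(r3, c(1.542, 4.105), tolerance = 1e-3)
  cp <- critical_points(c(A = 30, B = 0.751, C = 2.824))
  expect_equal(r3, unname(cp$points[c("MAP", "MDP")]), tolerance = 1e-6)
  # u = exp(-B(x - C)) at the third-derivative roots
  u <- exp(-0.751 * (r3 - 2.824))
  expect_equal(u, c(2.618, 0.382), tolerance = 1e-4)
  # parameter sweep
  set.seed(31)
  for (i in 1:25) {
    p <- c(A = runif(1, 10, 50), B = runif(1, 0.3, 3), C = runif(1, 1, 4))
    cp <- critical_points(p)
    expect_equal(derivative_roots(p, order = 3),
                 unname(cp$points[c("MAP", "MDP")]), tolerance = 1e-6)
    expect_equal(derivative_roots(p, order = 2), p[["C"]], tolerance = 1e-6)
  }
})

test_that("degenerate critical-point inputs are rejected", {
  expect_error(critical_points(c(A = 0.5, B = 1, C = 2)), "threshold")
  expect_error(derivative_roots(PAR8, order = 1), "order")
})

test_that("stage table partitions the root with the expected rates", {
  p <- c(A = 23.18, B = 0.751, C = 3.012)
  st <- stage_table(p, root_length = 12)
  expect_equal(nrow(st), 5)
  # contiguous, ordered, no gaps
  expect_equal(st$start[-1], st$end[-5])
  expect_equal(st$start[1], 0)
  expect_equal(st$end[5], 11)
  # the rapid stage is fastest
  expect_gt(st$rate[3], st$rate[2])
  expect_gt(st$rate[3], st$rate[4])
  # Stage III rate is 0.31665*A*B independent of C, ~5.5 %/cm here
  expect_equal(st$rate[3], stage3_rate(23.18, 0.751))
  expect_equal(stage3_rate(23.18, 0.751), 0.31665 * 23.18 * 0.751,
               tolerance = 2e-4)
  shifted <- stage_table(c(A = 23.18, B = 0.751, C = 4), root_length = 12)
  expect_equal(shifted$rate[3], st$rate[3])
})

test_that("censored points truncate the stage table", {
  p <- c(A = 23.18, B = 0.751, C = 3.012)
  st <- stage_table(p, root_length = 4)
  expect_lte(nrow(st), 3)
  expect_equal(st$stage[1:2], c("I (lag)", "II (starting)"))
})

test_that("critical points move apexward as roots lengthen", {
  cps <- t(sapply(4:16, function(L) {
    critical_points(predict_params(L), root_length = Inf)$points
  }))
  for (col in c("IP", "MDP")) {
    expect_true(all(diff(cps[, col]) <= 1e-9))
  }
  # MAP declines steadily in the short regime and overall, but wobbles
  # around the regime boundary (as the published per-length values do)
  short <- 1:9   # rows for L = 4..12
  expect_true(all(diff(cps[short, "MAP"]) <= 1e-9))
  expect_lt(cps[13, "MAP"], cps[1, "MAP"])
})
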