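#' Sigmoid model families for aerenchyma profiles
#'
#' Four three-parameter sigmoid families are supported, each mapping distance
#' from the root apex `x` (cm) to aerenchyma percentage (%):
#'
#' * `ti_gompertz`: \eqn{y = A \exp(-\exp(-B(x - C)))} — the inflection-point
#'   parameterization; `C` is the abscissa of the inflection point (cm).
#' * `w0_gompertz`: \eqn{y = A \exp(-C \exp(-B x))} — the classical form whose
#'   location parameter `C` encodes the initial value (\eqn{y(0) = A e^{-C}}).
#' * `logistic`: \eqn{y = A / (1 + \exp(C - B x))}.
#' * `von_bertalanffy`: \eqn{y = A (1 - C \exp(-B x))^3}.
#'
#' In all families `A` is the upper asymptote (%) and `B` a rate parameter
#' (per cm); the meaning of `C` varies by family.
#'
#' @return `growth_families()` returns the character vector of the four
#'   family names.
#' @examples
#' growth_families()
#' growth_curve("ti_gompertz", c(A = 44.8, B = 1.156, C = 2.206), x = 0:16)
#' @export
growth_families <- function() {
  c("w0_gompertz", "ti_gompertz", "logistic", "von_bertalanffy")
}

check_family <- function(family) {
  if (!is.character(family) || length(family) != 1L ||
      !family %in% growth_families()) {
    stop("unknown model family: ", paste(family, collapse = ", "),
         " (must be one of ", paste(growth_families(), collapse = ", "), ")",
         call. = FALSE)
  }
  family
}

check_params <- function(params) {
  if (is.list(params)) params <- unlist(params)
  if (!is.numeric(params) || length(params) != 3L) {
    stop("params must be a numeric vector of length 3 (A, B, C)",
         call. = FALSE)
  }
  if (is.null(names(params)) || !all(c("A", "B", "C") %in% names(params))) {
    names(params) <- c("A", "B", "C")
  }
  params <- params[c("A", "B", "C")]
  if (any(!is.finite(params))) {
    stop("non-finite model parameter: ",
         paste(names(params)[!is.finite(params)], collapse = ", "),
         call. = FALSE)
  }
  params
}

#' Evaluate a sigmoid model family
#'
#' @param family One of [growth_families()].
#' @param params Named numeric vector `c(A = , B = , C = )`.
#' @param x Distance from the root apex (cm); vectorized.
#' @return Aerenchyma percentage at `x` (same length as `x`).
#' @export
growth_curve <- function(family, params, x) {
  family <- check_family(family)
  p <- check_params(params)
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  A <- p[["A"]]; B <- p[["B"]]; C <- p[["C"]]
  switch(family,
    ti_gompertz     = A * exp(-exp(-B * (x - C))),
    w0_gompertz     = A * exp(-C * exp(-B * x)),
    logistic        = A / (1 + exp(C - B * x)),
    von_bertalanffy = A * (1 - C * exp(-B * x))^3
  )
}

#' Derivatives of a sigmoid model family
#'
#' Analytic first to third derivatives for the two Gompertz forms; analytic
#' first and second, numeric third (central difference on the analytic second,
#' step `1e-4 * max(1, |x|)`) for the logistic and von Bertalanffy families.
#' Only the Ti-Gompertz derivatives feed the downstream critical-point
#' machinery, where the third derivative's roots define the maximum
#' acceleration and deceleration points.
#'
#' @inheritParams growth_curve
#' @param order Derivative order, 1, 2 or 3.
#' @return Derivative of aerenchyma percentage with respect to distance
#'   (% per cm^order), vectorized over `x`.
#' @export
growth_deriv <- function(family, params, x, order = 1) {
  family <- check_family(family)
  p <- check_params(params)
  if (!order %in% c(1, 2, 3)) {
    stop("derivative order must be 1, 2 or 3", call. = FALSE)
  }
  A <- p[["A"]]; B <- p[["B"]]; C <- p[["C"]]
  if (family == "ti_gompertz") {
    u <- exp(-B * (x - C))
    base <- A * B * u * exp(-u)
    return(switch(as.character(order),
      "1" = base,
      "2" = B * base * (u - 1),
      "3" = B^2 * base * (u^2 - 3 * u + 1)
    ))
  }
  if (family == "w0_gompertz") {
    # identical curve to ti form with C_ti = log(C)/B
    v <- C * exp(-B * x)          # = u of the ti form
    base <- A * B * v * exp(-v)
    return(switch(as.character(order),
      "1" = base,
      "2" = B * base * (v - 1),
      "3" = B^2 * base * (v^2 - 3 * v + 1)
    ))
  }
  if (family == "logistic") {
    s <- 1 / (1 + exp(C - B * x))
    d1 <- A * B * s * (1 - s)
    d2 <- A * B^2 * s * (1 - s) * (1 - 2 * s)
    if (order == 1) return(d1)
    if (order == 2) return(d2)
    return(num_third_deriv(family, p, x))
  }
  # von Bertalanffy: y = A(1 - v)^3 with v = C exp(-Bx)
  v <- C * exp(-B * x)
  d1 <- 3 * A * B * v * (1 - v)^2
  d2 <- -3 * A * B^2 * v * (1 - v) * (1 - 3 * v)
  if (order == 1) return(d1)
  if (order == 2) return(d2)
  num_third_deriv(family, p, x)
}

# central difference on the analytic second derivative
num_third_deriv <- function(family, params, x) {
  h <- 1e-4 * pmax(1, abs(x))
  (growth_deriv(family, params, x + h, 2) -
     growth_deriv(family, params, x - h, 2)) / (2 * h)
}

#' Convert between the two Gompertz parameterizations
#'
#' The W0 and Ti forms describe the same curve: with `A` and `B` shared,
#' `C_ti = log(C_w0) / B` and `C_w0 = exp(B * C_ti)`. The conversion is exact
#' and the round trip is the identity.
#'
#' @param params Named numeric vector `c(A, B, C)` in the `from` form.
#' @param from,to `"w0_gompertz"` or `"ti_gompertz"`.
#' @return Parameters in the `to` form.
#' @examples
#' gompertz_convert(c(A = 10, B = 1, C = exp(1)),
#'                  from = "w0_gompertz", to = "ti_gompertz")
#' @export
gompertz_convert <- function(params, from, to) {
  from <- check_family(from)
  to <- check_family(to)
  gomp <- c("w0_gompertz", "ti_gompertz")
  if (!from %in% gomp || !to %in% gomp) {
    stop("conversion is defined only between the two Gompertz forms",
         call. = FALSE)
  }
  p <- check_params(params)
  if (from == to) return(p)
  B <- p[["B"]]
  if (from == "w0_gompertz") {
    if (p[["C"]] <= 0) stop("W0-form C must be positive", call. = FALSE)
    p[["C"]] <- log(p[["C"]]) / B
  } else {
    p[["C"]] <- exp(B * p[["C"]])
  }
  p
}

#' Definite integral of a sigmoid model curve
#'
#' Adaptive quadrature ([stats::integrate()], absolute tolerance `abs_tol`,
#' default 1e-8) of the curve over `[lower, upper]`, with a composite-Simpson
#' fallback (10,000 panels) if the adaptive routine fails. The Gompertz
#' integral has no elementary closed form.
#'
#' @inheritParams growth_curve
#' @param lower,upper Integration bounds (cm), `lower <= upper`.
#' @param abs_tol Absolute tolerance for the adaptive quadrature.
#' @return The integral in units of %·cm.
#' @export
growth_integral <- function(family, params, lower, upper, abs_tol = 1e-8) {
  family <- check_family(family)
  p <- check_params(params)
  if (!is.finite(lower) || !is.finite(upper)) {
    stop("integration bounds must be finite", call. = FALSE)
  }
  if (lower > upper) stop("lower bound exceeds upper bound", call. = FALSE)
  if (lower == upper) return(0)
  f <- function(x) growth_curve(family, p, x)
  val <- tryCatch(
    stats::integrate(f, lower, upper, abs.tol = abs_tol,
                     rel.tol = .Machine$double.eps^0.5)$value,
    error = function(e) simpson(f, lower, upper, n = 10000L)
  )
  val
}

# composite Simpson rule on n panels (n even)
simpson <- function(f, a, b, n = 10000L) {
  if (n %% 2L == 1L) n <- n + 1L
  x <- seq(a, b, length.out = n + 1L)
  y <- f(x)
  h <- (b - a) / n
  h / 3 * (y[1] + y[n + 1] +
             4 * sum(y[seq(2, n, by = 2)]) +
             2 * sum(y[seq(3, n - 1, by = 2)]))
}
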