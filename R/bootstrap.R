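#' Residual bootstrap of a fitted sigmoid model
#'
#' Resamples the mean-centered residuals of the fit (with replacement) onto
#' the fitted values, refits the same family from the OLS estimate as the
#' starting point, and summarizes the resulting parameter sampling
#' distribution: bootstrap mean and SD, percentile 95% CI (2.5th and 97.5th
#' percentiles) and its width, bias relative to the OLS estimate, and sample
#' skewness. The residuals, not the (x, y) pairs, are resampled because the
#' abscissae form a fixed sectioning grid. Replicates that fail to converge
#' are dropped and counted.
#'
#' @param fit A converged [fit_profile()] result.
#' @param n_boot Number of bootstrap replicates (default 1000; fewer than 100
#'   draws a warning).
#' @param seed Optional RNG seed; the run is fully reproducible given a seed.
#' @return An object of class `aer_bootstrap`: a list with `estimates` (the
#'   matrix of converged replicate estimates), `summary` (a data frame with
#'   one row per parameter: `ols`, `boot_mean`, `boot_sd`, `ci_low`,
#'   `ci_high`, `ci_width`, `bias`, `skewness`), `n_boot` and `n_failed`.
#' @examples
#' pr <- generate_profile(8, generator_config(seed = 7))
#' fit <- fit_profile(pr, "ti_gompertz")
#' bs <- residual_bootstrap(fit, n_boot = 200, seed = 1)
#' bs$summary
#' @export
residual_bootstrap <- function(fit, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(fit, "aer_fit"))
  if (!fit$converged) stop("bootstrap requires a converged fit", call. = FALSE)
  if (n_boot < 100) {
    warning("n_boot < 100 gives unstable percentile intervals", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- fit$data$position
  yhat <- fit$data$fitted
  res <- fit$data$value - yhat
  res <- res - mean(res)
  bounds <- param_bounds(fit$family)
  control <- minpack.lm::nls.lm.control(gtol = 1e-8, ftol = 1e-12,
                                        ptol = 1e-12, maxfev = 2000L)
  est <- matrix(NA_real_, nrow = n_boot, ncol = 3L,
                dimnames = list(NULL, c("A", "B", "C")))
  for (b in seq_len(n_boot)) {
    y_star <- yhat + sample(res, replace = TRUE)
    res_fun <- function(p) {
      y_star - growth_curve(fit$family, c(A = p[1], B = p[2], C = p[3]), x)
    }
    lm_fit <- tryCatch(
      minpack.lm::nls.lm(par = unname(fit$params), fn = res_fun,
                         lower = bounds$lower, upper = bounds$upper,
                         control = control),
      error = function(e) NULL
    )
    if (!is.null(lm_fit) && lm_fit$info %in% 1:4) est[b, ] <- lm_fit$par
  }
  ok <- stats::complete.cases(est)
  n_failed <- sum(!ok)
  if (n_failed > n_boot / 2) {
    stop("more than half of the bootstrap refits failed to converge",
         call. = FALSE)
  }
  est <- est[ok, , drop = FALSE]
  summ <- do.call(rbind, lapply(c("A", "B", "C"), function(pn) {
    v <- est[, pn]
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(parameter = pn,
               ols = fit$params[[pn]],
               boot_mean = mean(v),
               boot_sd = stats::sd(v),
               ci_low = q[1], ci_high = q[2], ci_width = q[2] - q[1],
               bias = mean(v) - fit$params[[pn]],
               skewness = sample_skewness(v))
  }))
  rownames(summ) <- NULL
  structure(list(estimates = est, summary = summ,
                 n_boot = n_boot, n_failed = n_failed,
                 family = fit$family),
            class = "aer_bootstrap")
}

#' @export
print.aer_bootstrap <- function(x, digits = 4, ...) {
  cat(sprintf("Residual bootstrap of a %s fit: %d replicates (%d failed)\n",
              x$family, x$n_boot, x$n_failed))
  print(x$summary, digits = digits, row.names = FALSE)
  invisible(x)
}

# sample skewness m3 / m2^(3/2); 0 for (near-)constant input
sample_skewness <- function(v) {
  m2 <- mean((v - mean(v))^2)
  if (m2 < .Machine$double.eps) return(0)
  mean((v - mean(v))^3) / m2^1.5
}

#' Density summary of bootstrap parameter estimates
#'
#' Gaussian-kernel density of the replicate estimates, renormalized so that
#' its trapezoid integral over the evaluation grid is exactly 1; constant
#' input yields a point-mass representation instead. The returned object
#' supports probability queries \eqn{P(a \le x \le b) = \int_a^b f(x)\,dx}.
#'
#' @param estimates Numeric vector of at least 100 parameter estimates.
#' @param ... Passed to [stats::density()].
#' @return An object of class `aer_density`: a list with `type` (`"density"`
#'   or `"point_mass"`), the grid `x` and values `y` (or `at` for a point
#'   mass), and the input size `n`.
#' @seealso [prob_between()]
#' @export
density_summary <- function(estimates, ...) {
  estimates <- estimates[is.finite(estimates)]
  if (length(estimates) < 100L) {
    stop("need at least 100 estimates for a density summary", call. = FALSE)
  }
  if (stats::sd(estimates) < .Machine$double.eps) {
    return(structure(list(type = "point_mass", at = estimates[1],
                          n = length(estimates)),
                     class = "aer_density"))
  }
  d <- stats::density(estimates, ...)
  total <- trapezoid(d$x, d$y)
  structure(list(type = "density", x = d$x, y = d$y / total,
                 n = length(estimates), bw = d$bw),
            class = "aer_density")
}

#' Probability mass of a density summary over an interval
#'
#' @param density An [density_summary()] result.
#' @param a,b Interval bounds, `a <= b`.
#' @return \eqn{P(a \le x \le b)} under the summarized density.
#' @export
prob_between <- function(density, a, b) {
  stopifnot(inherits(density, "aer_density"), a <= b)
  if (density$type == "point_mass") {
    return(as.numeric(density$at >= a & density$at <= b))
  }
  keep <- density$x >= a & density$x <= b
  if (sum(keep) < 2L) return(0)
  trapezoid(density$x[keep], density$y[keep])
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Parameter-bias verdicts from a bootstrap
#'
#' Flags a parameter as biased when the relative bootstrap bias exceeds
#' `bias_threshold` (default 5% of the OLS estimate) or when the sampling
#' distribution is markedly asymmetric (|skewness| above `skew_threshold`,
#' default 1).
#'
#' @param fit The OLS [fit_profile()] result.
#' @param boot The matching [residual_bootstrap()] summary.
#' @param bias_threshold Relative-bias threshold.
#' @param skew_threshold Absolute-skewness threshold.
#' @return A data frame with one row per parameter: `ols`, `boot_mean`,
#'   `bias`, `rel_bias`, `skewness`, and logical `biased`.
#' @export
bias_report <- function(fit, boot, bias_threshold = 0.05, skew_threshold = 1) {
  stopifnot(inherits(fit, "aer_fit"), inherits(boot, "aer_bootstrap"))
  if (fit$family != boot$family) {
    stop("fit and bootstrap are for different model families", call. = FALSE)
  }
  s <- boot$summary
  rel_bias <- abs(s$bias) / pmax(abs(s$ols), .Machine$double.eps)
  data.frame(parameter = s$parameter,
             ols = s$ols, boot_mean = s$boot_mean,
             bias = s$bias, rel_bias = rel_bias,
             skewness = s$skewness,
             biased = rel_bias > bias_threshold |
               abs(s$skewness) > skew_threshold)
}
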