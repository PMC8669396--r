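#' Fit a sigmoid model to an aerenchyma profile
#'
#' Ordinary least squares on the per-position mean aerenchyma percentages
#' (replicates are averaged within each position; the basal exclusion segment
#' is dropped), by Levenberg-Marquardt via [minpack.lm::nls.lm()]. Box bounds
#' keep `A` in (0, 100] (a percentage cannot exceed 100) and `B` in (0, 50];
#' `C` is unbounded except for the von Bertalanffy family where `C` must lie
#' in (0, 1] for the curve to start near zero and grow.
#'
#' @param profile A [root_profile()].
#' @param family One of [growth_families()] (default `"ti_gompertz"`).
#' @param start Optional named starting values `c(A, B, C)`; defaults to
#'   [default_start()].
#' @param use_replicates If `TRUE`, fit all replicate points instead of the
#'   per-position means.
#' @param control Passed to [minpack.lm::nls.lm.control()]; defaults to
#'   gradient tolerance 1e-8 and at most 2000 function evaluations.
#' @return An object of class `aer_fit` with components `family`, `params`
#'   (named `A`, `B`, `C`), `n`, `p`, `SSR`, `R2`, `AIC`, `BIC`, `converged`,
#'   `start`, `data` (the fitted positions and responses) and `profile`.
#' @seealso [compare_models()], [residual_bootstrap()], [critical_points()]
#' @examples
#' pr <- generate_profile(8, generator_config(noise_sd = 0, seed = 1))
#' fit <- fit_profile(pr, "ti_gompertz")
#' coef(fit)
#' summary(fit)
#' @export
fit_profile <- function(profile, family = "ti_gompertz", start = NULL,
                        use_replicates = FALSE, control = NULL) {
  stopifnot(inherits(profile, "root_profile"))
  family <- check_family(family)
  m <- profile_means(profile)
  if (nrow(m) < 4L) {
    stop("too few usable positions after basal exclusion (need >= 4, have ",
         nrow(m), ")", call. = FALSE)
  }
  if (use_replicates) {
    keep <- fitting_index(profile)
    x <- rep(profile$positions[keep], times = ncol(profile$values))
    y <- as.vector(profile$values[keep, , drop = FALSE])
  } else {
    x <- m$position
    y <- m$mean
  }
  if (is.null(start)) start <- default_start(profile, family)
  start <- check_params(start)
  if (is.null(control)) {
    control <- minpack.lm::nls.lm.control(gtol = 1e-8, ftol = 1e-12,
                                          ptol = 1e-12, maxfev = 2000L)
  }
  bounds <- param_bounds(family)
  start <- pmin(pmax(start, bounds$lower), bounds$upper)
  res_fun <- function(p) {
    y - growth_curve(family, c(A = p[1], B = p[2], C = p[3]), x)
  }
  lm_fit <- minpack.lm::nls.lm(par = unname(start), fn = res_fun,
                               lower = bounds$lower, upper = bounds$upper,
                               control = control)
  # codes 1-3: ftol/ptol criteria; 4: gradient-orthogonality (gtol) criterion
  converged <- lm_fit$info %in% 1:4
  if (!converged) {
    warning("fit did not converge (", family, "): ", lm_fit$message,
            call. = FALSE)
  }
  params <- stats::setNames(lm_fit$par, c("A", "B", "C"))
  yhat <- growth_curve(family, params, x)
  SSR <- sum((y - yhat)^2)
  SST <- sum((y - mean(y))^2)
  R2 <- if (SST > 0) 1 - SSR / SST else NA_real_
  n <- length(y)
  ic <- suppressWarnings(information_criteria(n, 3L, SSR))
  structure(
    list(family = family, params = params, n = n, p = 3L,
         SSR = SSR, R2 = R2, AIC = ic[["AIC"]], BIC = ic[["BIC"]],
         converged = converged, start = start,
         data = data.frame(position = x, value = y, fitted = yhat),
         profile = profile),
    class = "aer_fit"
  )
}

# box bounds used by fit_profile, per family; A is a percentage, B > 0 for a
# curve that saturates with distance, C > 0 where the form requires it
param_bounds <- function(family) {
  lower_C <- if (family %in% c("von_bertalanffy", "w0_gompertz")) 1e-8 else -Inf
  list(lower = c(1e-8, 1e-8, lower_C), upper = c(100, 50, Inf))
}

#' Heuristic starting values for a sigmoid fit
#'
#' `A` starts at 1.05 times the maximum per-position mean. The location and
#' rate start from the characteristic point of each family (the abscissa
#' where the mean first exceeds A/e for the Ti-Gompertz form, half-maximum
#' for the logistic) and the slope of the log-linearized interior points,
#' clamped to `[0.05, 10]`.
#'
#' @inheritParams fit_profile
#' @return Named starting values `c(A, B, C)`.
#' @export
default_start <- function(profile, family = "ti_gompertz") {
  stopifnot(inherits(profile, "root_profile"))
  family <- check_family(family)
  m <- profile_means(profile)
  if (max(m$mean) <= min(m$mean) || max(m$mean) <= 0) {
    stop("no aerenchyma signal in profile (degenerate means)", call. = FALSE)
  }
  A0 <- 1.05 * max(m$mean)
  x <- m$position
  frac <- pmin(pmax(m$mean / A0, 1e-6), 1 - 1e-6)
  interior <- which(frac > 0.05 & frac < 0.95)
  if (length(interior) < 2L) {
    interior <- order(abs(frac - 0.5))[1:2]
  }
  clamp_B <- function(b) min(max(b, 0.05), 10)
  if (family %in% c("ti_gompertz", "w0_gompertz")) {
    z <- -log(-log(frac))                 # linear in x with slope B
    B0 <- clamp_B(stats::coef(stats::lm(z[interior] ~ x[interior]))[[2]])
    target <- A0 / exp(1)
    C0 <- x[which(m$mean >= target)[1]]
    if (is.na(C0)) C0 <- stats::median(x)
    p <- c(A = A0, B = B0, C = C0)
    if (family == "w0_gompertz") {
      p <- gompertz_convert(p, from = "ti_gompertz", to = "w0_gompertz")
    }
    return(p)
  }
  if (family == "logistic") {
    z <- log(frac / (1 - frac))           # = Bx - C
    co <- stats::coef(stats::lm(z[interior] ~ x[interior]))
    B0 <- clamp_B(co[[2]])
    x_half <- x[which(m$mean >= A0 / 2)[1]]
    if (is.na(x_half)) x_half <- stats::median(x)
    return(c(A = A0, B = B0, C = B0 * x_half))
  }
  # von Bertalanffy: 1 - (y/A)^(1/3) = C exp(-Bx)
  z <- pmax(1 - frac^(1 / 3), 1e-8)
  co <- stats::coef(stats::lm(log(z[interior]) ~ x[interior]))
  B0 <- clamp_B(-co[[2]])
  C0 <- min(max(exp(co[[1]]), 1e-4), 1)
  c(A = A0, B = B0, C = C0)
}

#' Least-squares information criteria
#'
#' For a model with `p` parameters fitted by least squares to `n` points with
#' residual sum of squares `SSR`:
#' \deqn{AIC = n \ln(SSR/n) + 2p, \qquad BIC = n \ln(SSR/n) + p \ln(n).}
#' The additive constant common to all models is dropped, so only differences
#' between models fitted to the same data are meaningful. `variant =
#' "printed"` selects the alternative form `AIC = n + ln(SSR/n) + 2p` for
#' comparability with reports using that convention.
#'
#' @param n Number of fitted points.
#' @param p Number of parameters.
#' @param SSR Residual sum of squares.
#' @param variant `"standard"` (default) or `"printed"` for the AIC.
#' @return Named vector `c(AIC, BIC)`.
#' @examples
#' information_criteria(15, 3, 15)  # AIC 6, BIC 3*log(15)
#' @export
information_criteria <- function(n, p, SSR, variant = c("standard", "printed")) {
  variant <- match.arg(variant)
  stopifnot(n > p, SSR >= 0)
  if (SSR == 0) {
    warning("SSR is zero; information criteria are -Inf", call. = FALSE)
    return(c(AIC = -Inf, BIC = -Inf))
  }
  aic <- if (variant == "standard") n * log(SSR / n) + 2 * p
         else n + log(SSR / n) + 2 * p
  c(AIC = aic, BIC = n * log(SSR / n) + p * log(n))
}

#' Fit and rank all four model families on one profile
#'
#' Fits each of [growth_families()] to the profile and tabulates parameters
#' and goodness of fit, ranked by AIC (ascending), ties broken by BIC then
#' SSR. Families that fail to converge are flagged and ranked last.
#'
#' @inheritParams fit_profile
#' @return An object of class `aer_model_comparison`: a data frame with one
#'   row per family (`family`, `A`, `B`, `C`, `R2`, `SSR`, `AIC`, `BIC`,
#'   `converged`, `rank`), with the fit objects in attribute `"fits"`.
#' @export
compare_models <- function(profile, use_replicates = FALSE) {
  stopifnot(inherits(profile, "root_profile"))
  fits <- lapply(growth_families(), function(fam) {
    tryCatch(
      suppressWarnings(fit_profile(profile, fam, use_replicates = use_replicates)),
      error = function(e) NULL
    )
  })
  names(fits) <- growth_families()
  tab <- do.call(rbind, lapply(growth_families(), function(fam) {
    f <- fits[[fam]]
    if (is.null(f)) {
      data.frame(family = fam, A = NA, B = NA, C = NA, R2 = NA, SSR = NA,
                 AIC = NA, BIC = NA, converged = FALSE)
    } else {
      data.frame(family = fam, A = f$params[["A"]], B = f$params[["B"]],
                 C = f$params[["C"]], R2 = f$R2, SSR = f$SSR,
                 AIC = f$AIC, BIC = f$BIC, converged = f$converged)
    }
  }))
  ord <- order(!tab$converged, tab$AIC, tab$BIC, tab$SSR)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- ifelse(tab$converged, cumsum(tab$converged), NA_integer_)
  rownames(tab) <- NULL
  structure(tab, fits = fits, class = c("aer_model_comparison", "data.frame"))
}

#' @export
print.aer_model_comparison <- function(x, digits = 4, ...) {
  cat("Model comparison (ranked by AIC):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
print.aer_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit (%s)\n", x$family,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$params, digits))
  cat(sprintf("n = %d, SSR = %.4g, R2 = %.5f, AIC = %.3f, BIC = %.3f\n",
              x$n, x$SSR, x$R2, x$AIC, x$BIC))
  invisible(x)
}

#' @export
summary.aer_fit <- function(object, ...) {
  res <- stats::residuals(object)
  out <- list(fit = object,
              residual_summary = summary(res),
              sigma = sqrt(object$SSR / max(object$n - object$p, 1)))
  class(out) <- "summary.aer_fit"
  out
}

#' @export
print.summary.aer_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Residual standard error: %.4g on %d degrees of freedom\n",
              x$sigma, x$fit$n - x$fit$p))
  cat("Residuals:\n")
  print(x$residual_summary)
  invisible(x)
}

#' @export
coef.aer_fit <- function(object, ...) object$params

#' @export
fitted.aer_fit <- function(object, ...) object$data$fitted

#' @export
residuals.aer_fit <- function(object, ...) object$data$value - object$data$fitted

#' @export
deviance.aer_fit <- function(object, ...) object$SSR

#' Predict aerenchyma percentage from a fitted model
#'
#' @param object An `aer_fit`.
#' @param newdata Optional numeric vector of distances from the apex (cm), or
#'   a data frame with a `position` column; defaults to the fitted positions.
#' @param ... Unused.
#' @return Predicted aerenchyma percentages.
#' @export
predict.aer_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$data$fitted)
  x <- if (is.data.frame(newdata)) newdata$position else newdata
  growth_curve(object$family, object$params, x)
}

#' Simulate replicate profiles from a fitted model
#'
#' Draws `nsim` synthetic response vectors at the fitted positions, adding
#' residual-bootstrap noise (mean-centered fitted residuals resampled with
#' replacement) to the fitted curve.
#'
#' @param object An `aer_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data frame with one column per simulation.
#' @export
simulate.aer_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  res <- stats::residuals(object)
  res <- res - mean(res)
  out <- replicate(nsim, object$data$fitted + sample(res, replace = TRUE))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Plot a fitted aerenchyma profile
#'
#' @param x An `aer_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.aer_fit <- function(x, ...) {
  graphics::plot(x$data$position, x$data$value,
                 xlab = "Distance from root apex (cm)",
                 ylab = "Aerenchyma percentage (%)",
                 main = sprintf("%s fit", x$family), ...)
  grid_x <- seq(min(x$data$position), max(x$data$position), length.out = 200)
  graphics::lines(grid_x, growth_curve(x$family, x$params, grid_x), col = 2)
  invisible(x)
}
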