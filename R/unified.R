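#' Piecewise-linear dependence of Ti-Gompertz parameters on root length
#'
#' The Ti-Gompertz parameters fitted per root length follow two linear
#' regimes split at a breakpoint (13 cm): below it the asymptote grows
#' linearly with length while the rate is constant; at and above it the
#' asymptote is constant while the rate grows. Each parameter in each regime
#' is stored as `c(intercept, slope)`; a frozen (constant) parameter has
#' slope 0 and intercept equal to the regime mean.
#'
#' `unified_coefficients()` builds the object from explicit coefficients;
#' `default_unified_coefficients()` returns the published relations
#' (short regime, L < 13: A = 13.02 + 2.54 L, B = 0.751, C = 3.20 - 0.047 L;
#' long regime, L >= 13: A = 44.8, B = -0.748 + 0.119 L, C = 4.43 - 0.139 L).
#'
#' @param short,long Named lists with entries `A`, `B`, `C`, each a numeric
#'   `c(intercept, slope)`.
#' @param breakpoint Root length (cm) splitting the regimes; lengths
#'   `>= breakpoint` use the long regime.
#' @param pvalues Optional data frame of slope p-values per parameter/regime.
#' @return An object of class `unified_coefficients`.
#' @export
unified_coefficients <- function(short, long, breakpoint = 13, pvalues = NULL) {
  check_regime <- function(r, nm) {
    stopifnot(all(c("A", "B", "C") %in% names(r)))
    for (par in c("A", "B", "C")) {
      if (!is.numeric(r[[par]]) || length(r[[par]]) != 2L) {
        stop(nm, "-regime ", par, " must be c(intercept, slope)", call. = FALSE)
      }
    }
    lapply(r[c("A", "B", "C")], stats::setNames, c("intercept", "slope"))
  }
  structure(list(short = check_regime(short, "short"),
                 long = check_regime(long, "long"),
                 breakpoint = breakpoint,
                 pvalues = pvalues),
            class = "unified_coefficients")
}

#' @rdname unified_coefficients
#' @export
default_unified_coefficients <- function() {
  unified_coefficients(
    short = list(A = c(13.02, 2.54), B = c(0.751, 0), C = c(3.20, -0.047)),
    long = list(A = c(44.8, 0), B = c(-0.748, 0.119), C = c(4.43, -0.139)),
    breakpoint = 13
  )
}

#' @export
print.unified_coefficients <- function(x, digits = 4, ...) {
  fmt <- function(co, par) {
    if (abs(co[["slope"]]) < .Machine$double.eps) {
      sprintf("%s = %.*g (constant)", par, digits, co[["intercept"]])
    } else {
      sprintf("%s = %.*g %+.*g L", par, digits, co[["intercept"]],
              digits, co[["slope"]])
    }
  }
  cat(sprintf("Unified Ti-Gompertz coefficients (breakpoint %.4g cm)\n",
              x$breakpoint))
  cat(sprintf("  L < %.4g:  %s\n", x$breakpoint,
              paste(mapply(fmt, x$short, names(x$short)), collapse = "; ")))
  cat(sprintf("  L >= %.4g: %s\n", x$breakpoint,
              paste(mapply(fmt, x$long, names(x$long)), collapse = "; ")))
  if (!is.null(x$pvalues)) {
    cat("Slope p-values:\n")
    print(x$pvalues, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Regress per-length Ti-Gompertz parameters on root length
#'
#' Splits the per-length fits at the breakpoint and, within each regime,
#' regresses each of A, B, C on root length by ordinary simple linear
#' regression. A parameter is frozen to its regime mean when the slope's
#' two-sided p-value is at least `alpha` (default 0.05), reproducing the
#' constant rate below the breakpoint and the constant asymptote above it.
#'
#' @param fits A data frame with columns `L`, `A`, `B`, `C` (one row per root
#'   length), or a list of `aer_fit` objects (lengths taken from their
#'   profiles).
#' @param breakpoint Regime split (cm); `L >= breakpoint` is the long regime.
#' @param alpha Significance level below which a slope is retained.
#' @return A [unified_coefficients()] object with slope p-values attached.
#' @examples
#' L <- 4:16
#' pars <- t(sapply(L, predict_params))
#' fit <- fit_parameter_trends(data.frame(L = L, pars))
#' print(fit)
#' @export
fit_parameter_trends <- function(fits, breakpoint = 13, alpha = 0.05) {
  if (is.list(fits) && !is.data.frame(fits) &&
      all(vapply(fits, inherits, logical(1), "aer_fit"))) {
    fits <- data.frame(
      L = vapply(fits, function(f) f$profile$root_length_cm, numeric(1)),
      A = vapply(fits, function(f) f$params[["A"]], numeric(1)),
      B = vapply(fits, function(f) f$params[["B"]], numeric(1)),
      C = vapply(fits, function(f) f$params[["C"]], numeric(1))
    )
  }
  stopifnot(is.data.frame(fits), all(c("L", "A", "B", "C") %in% names(fits)))
  short <- fits[fits$L < breakpoint, , drop = FALSE]
  long <- fits[fits$L >= breakpoint, , drop = FALSE]
  if (nrow(short) < 3L || nrow(long) < 3L) {
    stop("need at least 3 root lengths in each regime (have ",
         nrow(short), " short, ", nrow(long), " long)", call. = FALSE)
  }
  fit_one <- function(d, par, regime) {
    y <- d[[par]]
    lmfit <- stats::lm(y ~ L, data = d)
    co <- stats::coef(lmfit)
    slope <- unname(co[["L"]])
    sigma <- sqrt(sum(stats::residuals(lmfit)^2) / lmfit$df.residual)
    pval <- if (sigma < 1e-10 * max(1, stats::sd(y))) {
      # noiseless data: an exact line has p = 0, an exact constant p = 1
      if (abs(slope) < 1e-10 * max(1, abs(mean(y)))) 1 else 0
    } else {
      summary(lmfit)$coefficients["L", "Pr(>|t|)"]
    }
    if (pval >= alpha) {
      list(coef = c(mean(y), 0), p = pval)
    } else {
      list(coef = c(unname(co[[1]]), slope), p = pval)
    }
  }
  res <- list()
  pv <- list()
  for (regime in c("short", "long")) {
    d <- if (regime == "short") short else long
    res[[regime]] <- list()
    for (par in c("A", "B", "C")) {
      r <- fit_one(d, par, regime)
      res[[regime]][[par]] <- r$coef
      pv[[length(pv) + 1L]] <- data.frame(regime = regime, parameter = par,
                                          slope_p = r$p,
                                          frozen = r$coef[2] == 0)
    }
  }
  unified_coefficients(res$short, res$long, breakpoint = breakpoint,
                       pvalues = do.call(rbind, pv))
}

#' Predict Ti-Gompertz parameters for a given root length
#'
#' Evaluates the piecewise-linear relations of a [unified_coefficients()]
#' object: lengths below the breakpoint use the short regime, lengths at or
#' above it the long regime. The supported range is 4-16 cm (warned outside;
#' shorter roots carry no aerenchyma and longer ones were not measured).
#'
#' @param L Root length (cm), positive scalar.
#' @param coef A [unified_coefficients()] object (default: the published
#'   relations).
#' @return Named Ti-Gompertz parameters `c(A, B, C)`.
#' @examples
#' predict_params(8)   # A = 33.34, B = 0.751, C = 2.824
#' predict_params(16)  # A = 44.8, B = 1.156, C = 2.206
#' @export
predict_params <- function(L, coef = default_unified_coefficients()) {
  stopifnot(inherits(coef, "unified_coefficients"),
            is.numeric(L), length(L) == 1L)
  if (L <= 0) stop("root length must be positive", call. = FALSE)
  if (L < 4 || L > 16) {
    warning("root length ", L, " cm is outside the supported 4-16 cm range",
            call. = FALSE)
  }
  regime <- if (L < coef$breakpoint) coef$short else coef$long
  vapply(regime, function(co) co[["intercept"]] + co[["slope"]] * L,
         numeric(1))
}

#' Predict aerenchyma percentage from root length and position
#'
#' Evaluates the unified Ti-Gompertz model: the parameters are predicted from
#' the root length via [predict_params()] and the curve is evaluated at the
#' distance `D` from the apex.
#'
#' @param L Root length (cm).
#' @param D Distance from the root apex (cm), vectorized, each in `[0, L]`.
#' @inheritParams predict_params
#' @return Predicted aerenchyma percentage(s).
#' @examples
#' predict_AR(8, 2.824)  # inflection point: 33.34 / e
#' @export
predict_AR <- function(L, D, coef = default_unified_coefficients()) {
  if (any(D < 0) || any(D > L)) {
    stop("distance from the apex must lie within [0, L]", call. = FALSE)
  }
  growth_curve("ti_gompertz", predict_params(L, coef), D)
}
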