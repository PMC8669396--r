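# Roots of u^2 - 3u + 1 = 0 where u = exp(-B(x - C)): the third derivative
# of the Ti-Gompertz curve vanishes at u = (3 +- sqrt(5))/2, i.e. 2.6180...
# (maximum acceleration) and 0.38197... (maximum deceleration).
U_MAP <- (3 + sqrt(5)) / 2
U_MDP <- (3 - sqrt(5)) / 2

#' Critical points of a Ti-Gompertz aerenchyma curve
#'
#' Closed-form abscissae (cm from the root apex) of the five biologically
#' meaningful critical points of \eqn{y = A \exp(-\exp(-B(x - C)))}:
#'
#' * `InP`, the initial point where the curve reaches the detection
#'   `threshold` (default 1%): \eqn{C - \ln(\ln(A/\mathrm{threshold}))/B};
#' * `MAP`, the maximum acceleration point \eqn{C - \ln((3+\sqrt5)/2)/B}
#'   (first root of the third derivative);
#' * `IP`, the inflection point, equal to `C` by construction (curve value
#'   `A/e`, 36.8% of the asymptote);
#' * `MDP`, the maximum deceleration point \eqn{C - \ln((3-\sqrt5)/2)/B};
#' * `MVP95`, where the curve reaches `mvp_frac` (default 95%) of `A`:
#'   \eqn{C - \ln(-\ln(\mathrm{mvp\_frac}))/B}.
#'
#' Points falling beyond the observable part of the root (abscissa greater
#' than `root_length - basal_exclusion`) are censored (`NA`); the inflection
#' point is exempt because it equals the fitted parameter `C`, which is
#' reported regardless of the observable range.
#'
#' @param params Ti-Gompertz parameters `c(A, B, C)` (or an `aer_fit`).
#' @param root_length Root length (cm); `Inf` disables censoring.
#' @param threshold Detection threshold defining the initial point (%).
#' @param mvp_frac Fraction of the asymptote defining the near-plateau point.
#' @param basal_exclusion Basal segment excluded from observation (cm).
#' @return An object of class `aer_critical_points`: a list with `points`
#'   (named vector `InP`, `MAP`, `IP`, `MDP`, `MVP95`, censored entries
#'   `NA`), `censored` (logical vector), `params` and the censoring limit.
#' @examples
#' cp <- critical_points(c(A = 33.34, B = 0.751, C = 2.824), root_length = 8)
#' cp$points
#' @export
critical_points <- function(params, root_length = Inf, threshold = 1,
                            mvp_frac = 0.95, basal_exclusion = 1) {
  if (inherits(params, "aer_fit")) {
    if (params$family != "ti_gompertz") {
      stop("critical points are defined for the ti_gompertz family",
           call. = FALSE)
    }
    params <- params$params
  }
  p <- check_params(params)
  A <- p[["A"]]; B <- p[["B"]]; C <- p[["C"]]
  stopifnot(B > 0, A > 0, threshold > 0, mvp_frac > 0, mvp_frac < 1)
  if (A / threshold <= 1) {
    stop("asymptote A does not exceed the detection threshold; ",
         "the initial point is undefined", call. = FALSE)
  }
  pts <- c(
    InP = C - log(log(A / threshold)) / B,
    MAP = C - log(U_MAP) / B,
    IP = C,
    MDP = C - log(U_MDP) / B,
    MVP95 = C - log(-log(mvp_frac)) / B
  )
  limit <- root_length - basal_exclusion
  censored <- stats::setNames(pts > limit, names(pts))
  censored[["IP"]] <- FALSE   # the parameter C is always reported
  pts[censored] <- NA_real_
  structure(list(points = pts, censored = censored, params = p,
                 root_length = root_length, threshold = threshold,
                 mvp_frac = mvp_frac, basal_exclusion = basal_exclusion,
                 limit = limit),
            class = "aer_critical_points")
}

#' @export
print.aer_critical_points <- function(x, digits = 3, ...) {
  cat("Ti-Gompertz critical points (cm from root apex):\n")
  shown <- ifelse(is.na(x$points), "-", format(round(x$points, digits)))
  print(stats::setNames(shown, names(x$points)), quote = FALSE)
  if (any(x$censored)) {
    cat(sprintf("censored beyond %.2f cm (root length %.1f cm minus %.1f cm basal exclusion)\n",
                x$limit, x$root_length, x$basal_exclusion))
  }
  invisible(x)
}

#' Numeric roots of a Ti-Gompertz derivative
#'
#' An independent check on the closed forms: brackets sign changes of the
#' analytic derivative of the given order on a grid over
#' `[C - 10/B, C + 10/B]` and polishes each root by bisection
#' ([stats::uniroot()]) to `tol`. The single second-derivative root is the
#' inflection point; the two third-derivative roots are the maximum
#' acceleration and deceleration points.
#'
#' @param params Ti-Gompertz parameters `c(A, B, C)`.
#' @param order Derivative order whose roots are sought (2 or 3).
#' @param tol Absolute root tolerance (default 1e-8).
#' @return Sorted numeric vector of root abscissae (cm).
#' @export
derivative_roots <- function(params, order = 3, tol = 1e-8) {
  p <- check_params(params)
  if (!order %in% c(2, 3)) stop("order must be 2 or 3", call. = FALSE)
  B <- p[["B"]]; C <- p[["C"]]
  stopifnot(B > 0)
  lo <- C - 10 / B
  hi <- C + 10 / B
  grid <- seq(lo, hi, length.out = 2001L)
  f <- function(x) growth_deriv("ti_gompertz", p, x, order = order)
  fx <- f(grid)
  # strict sign changes (the derivative underflows to exactly zero in the
  # far tails, which must not be mistaken for roots), plus grid points that
  # hit a crossing exactly
  n <- length(fx)
  sign_change <- which(fx[-n] * fx[-1] < 0)
  hit <- which(fx == 0)
  hit <- hit[hit > 1 & hit < n & fx[pmax(hit - 1, 1)] * fx[pmin(hit + 1, n)] < 0]
  if (length(sign_change) == 0L && length(hit) == 0L) {
    stop("no sign change of the order-", order, " derivative found",
         call. = FALSE)
  }
  roots <- vapply(sign_change, function(i) {
    stats::uniroot(f, lower = grid[i], upper = grid[i + 1], tol = tol)$root
  }, numeric(1))
  sort(unique(c(roots, grid[hit])))
}

#' Five-stage decomposition of aerenchyma formation
#'
#' Splits the formation profile at the critical points into the lag stage
#' (Stage I, apex to initial point), the starting stage (II, initial point to
#' maximum acceleration), the rapid stage (III, maximum acceleration to
#' maximum deceleration), the temperate stage (IV, maximum deceleration to
#' 95% of maximum), and the plateau (V, onwards to the end of the observable
#' root). The mean formation rate of a stage is the chord slope
#' \eqn{(y(\mathrm{end}) - y(\mathrm{start})) / (\mathrm{end} -
#' \mathrm{start})} in % per cm. Censored critical points truncate the table
#' after the last defined boundary.
#'
#' @param params Ti-Gompertz parameters `c(A, B, C)`.
#' @param cps A matching [critical_points()] result (computed from `params`
#'   if omitted).
#' @param root_length,basal_exclusion Used only when `cps` is omitted.
#' @return A data frame with columns `stage`, `start`, `end`, `rate`.
#' @export
stage_table <- function(params, cps = NULL, root_length = Inf,
                        basal_exclusion = 1) {
  p <- check_params(params)
  if (is.null(cps)) {
    cps <- critical_points(p, root_length = root_length,
                           basal_exclusion = basal_exclusion)
  }
  stopifnot(inherits(cps, "aer_critical_points"))
  end_of_root <- if (is.finite(cps$limit)) cps$limit else Inf
  bounds <- c(0, cps$points[["InP"]], cps$points[["MAP"]],
              cps$points[["MDP"]], cps$points[["MVP95"]], end_of_root)
  labels <- c("I (lag)", "II (starting)", "III (rapid)",
              "IV (temperate)", "V (plateau)")
  rows <- list()
  for (k in seq_along(labels)) {
    s <- bounds[k]; e <- bounds[k + 1]
    if (is.na(s) || is.na(e)) break
    rate <- if (is.finite(s) && is.finite(e) && e > s) {
      (growth_curve("ti_gompertz", p, e) -
         growth_curve("ti_gompertz", p, s)) / (e - s)
    } else NA_real_
    rows[[k]] <- data.frame(stage = labels[k], start = s, end = e,
                            rate = rate)
  }
  do.call(rbind, rows)
}

#' Mean formation rate of the rapid stage
#'
#' Over Stage III (maximum acceleration to maximum deceleration point) the
#' Ti-Gompertz chord slope reduces to the closed form
#' \eqn{A B (e^{-u_2} - e^{-u_1}) / (\ln u_1 - \ln u_2)} with
#' \eqn{u_{1,2} = (3 \pm \sqrt5)/2}, i.e. approximately `0.31665 * A * B`,
#' independent of the location parameter `C`.
#'
#' @param A,B Ti-Gompertz asymptote and rate parameters.
#' @return Mean rate of Stage III (% per cm).
#' @export
stage3_rate <- function(A, B) {
  A * B * (exp(-U_MDP) - exp(-U_MAP)) / (log(U_MAP) - log(U_MDP))
}
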