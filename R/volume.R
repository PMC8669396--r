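#' Whole-root aerenchyma volume
#'
#' Treats the root as a cylinder of the given mean diameter and integrates
#' the aerenchyma-percentage curve along its axis:
#' \deqn{V = \frac{\pi d^2}{4} \int_{x_0}^{x_1} \frac{AR(x)}{100}\, dx,}
#' with the axial coordinate converted from cm to mm, so the result is in
#' mm^3. The curve comes either from explicit Ti-Gompertz parameters or from
#' the unified length-dependent model. Bounds default to the whole root
#' `[0, L]`; pass narrower bounds to exclude, e.g., the basal segment.
#'
#' @param L Root length (cm).
#' @param mean_diameter Mean root diameter (mm), positive.
#' @param params Optional Ti-Gompertz parameters `c(A, B, C)` (or an
#'   `aer_fit`); if omitted, parameters are predicted from `L` via `coef`.
#' @param coef [unified_coefficients()] used when `params` is missing.
#' @param bounds Integration bounds (cm) within `[0, L]`.
#' @return An object of class `aer_volume`: a list with `volume_mm3`,
#'   `root_length_cm`, `mean_diameter_mm`, `bounds` and `params`.
#' @examples
#' aerenchyma_volume(16, mean_diameter = 1)
#' @export
aerenchyma_volume <- function(L, mean_diameter, params = NULL,
                              coef = default_unified_coefficients(),
                              bounds = c(0, L)) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  if (!is.numeric(mean_diameter) || mean_diameter <= 0) {
    stop("mean diameter must be positive", call. = FALSE)
  }
  if (length(bounds) != 2L || bounds[1] > bounds[2] ||
      bounds[1] < 0 || bounds[2] > L + 1e-9) {
    stop("integration bounds must satisfy 0 <= lower <= upper <= L",
         call. = FALSE)
  }
  if (is.null(params)) {
    params <- predict_params(L, coef)
  } else if (inherits(params, "aer_fit")) {
    if (params$family != "ti_gompertz") {
      stop("volume integration uses the ti_gompertz family", call. = FALSE)
    }
    params <- params$params
  }
  params <- check_params(params)
  area_mm2 <- pi * mean_diameter^2 / 4
  integral_pct_cm <- growth_integral("ti_gompertz", params,
                                     bounds[1], bounds[2])
  volume <- area_mm2 * (integral_pct_cm / 100) * 10   # cm -> mm axially
  structure(list(volume_mm3 = volume, root_length_cm = L,
                 mean_diameter_mm = mean_diameter, bounds = bounds,
                 params = params),
            class = "aer_volume")
}

#' @export
print.aer_volume <- function(x, ...) {
  cat(sprintf(
    "Aerenchyma volume: %.4g mm^3 (root %.1f cm x %.2f mm, integrated over [%.2f, %.2f] cm)\n",
    x$volume_mm3, x$root_length_cm, x$mean_diameter_mm,
    x$bounds[1], x$bounds[2]))
  invisible(x)
}
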