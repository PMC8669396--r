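#' Run the full aerenchyma modelling pipeline
#'
#' Ties all stages together: load profiles from a long-format CSV (or
#' simulate them), fit the four model families per root length, bootstrap the
#' Ti-Gompertz fits, extract critical points, unify the parameters as
#' piecewise-linear functions of root length, and integrate the unified
#' curves into whole-root volumes. Writes five outputs to `out_dir`:
#'
#' * `model_comparison.csv` — family x root length x (params, R2, SSR, AIC, BIC);
#' * `bootstrap_summary.csv` — per-length, per-parameter bootstrap summary;
#' * `critical_points.csv` — critical-point abscissae per root length;
#' * `unified_coefficients.json` — the fitted piecewise-linear relations;
#' * `volumes.csv` — aerenchyma volume per root length;
#'
#' plus `run_log.txt` recording the seed, package version and configuration
#' hash. Given the same inputs and seed the outputs are byte-identical.
#'
#' @param input Path to a profiles CSV (schema of [read_profiles_csv()]), or
#'   `NULL` to simulate with `config`.
#' @param out_dir Output directory (created if needed).
#' @param config [generator_config()] used when simulating; its seed governs
#'   all randomness unless `seed` is given.
#' @param seed Overrides the config seed (also seeds the bootstrap).
#' @param n_boot Bootstrap replicates per root length.
#' @param breakpoint,threshold,mvp_frac,basal_exclusion Analysis settings,
#'   see [fit_parameter_trends()] and [critical_points()].
#' @param mean_diameter Mean root diameter (mm) for the volume estimates.
#' @param aic_variant `"standard"` or `"printed"`, see
#'   [information_criteria()].
#' @param overwrite Allow overwriting existing outputs.
#' @return Invisibly, a list with the in-memory results (`comparison`,
#'   `bootstrap`, `critical_points`, `unified`, `volumes`, `fits`).
#' @export
run_pipeline <- function(input = NULL, out_dir, config = generator_config(),
                         seed = NULL, n_boot = 1000, breakpoint = 13,
                         threshold = 1, mvp_frac = 0.95, basal_exclusion = 1,
                         mean_diameter = 1, aic_variant = "standard",
                         overwrite = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- file.path(out_dir, c("model_comparison.csv",
                                  "bootstrap_summary.csv",
                                  "critical_points.csv",
                                  "unified_coefficients.json",
                                  "volumes.csv", "run_log.txt"))
  if (!overwrite && any(file.exists(outputs))) {
    stop("output files already exist in ", out_dir,
         " (use overwrite = TRUE)", call. = FALSE)
  }
  if (!is.null(seed)) {
    config <- generator_config(
      root_lengths = config$root_lengths, step = config$step,
      n_rep = config$n_rep, noise_sd = config$noise_sd,
      detection_threshold = config$detection_threshold,
      basal_exclusion = basal_exclusion, seed = seed,
      noise_model = config$noise_model, coef = config$coef)
  }
  profiles <- if (is.null(input)) {
    generate_dataset(config)
  } else {
    read_profiles_csv(input, basal_exclusion_cm = basal_exclusion)
  }
  lengths <- vapply(profiles, function(p) p$root_length_cm, numeric(1))
  usable <- vapply(profiles, function(p) {
    m <- profile_means(p)
    nrow(m) >= 4 && max(m$mean) > min(m$mean)
  }, logical(1))

  comparison <- do.call(rbind, lapply(which(usable), function(i) {
    tab <- compare_models(profiles[[i]])
    cbind(root_length_cm = unname(lengths[i]), as.data.frame(tab))
  }))
  rownames(comparison) <- NULL
  if (aic_variant == "printed") {
    for (r in seq_len(nrow(comparison))) {
      n_pts <- sum(fitting_index(
        profiles[[sprintf("L%g", comparison$root_length_cm[r])]]))
      comparison$AIC[r] <- information_criteria(
        n_pts, 3L, comparison$SSR[r], variant = "printed")[["AIC"]]
    }
  }

  ti_fits <- lapply(which(usable), function(i) {
    suppressWarnings(fit_profile(profiles[[i]], "ti_gompertz"))
  })
  names(ti_fits) <- names(profiles)[usable]

  base_seed <- config$seed
  boot_rows <- list()
  for (i in seq_along(ti_fits)) {
    f <- ti_fits[[i]]
    if (!f$converged) next
    bs <- suppressWarnings(residual_bootstrap(
      f, n_boot = n_boot,
      seed = (base_seed * 131L + i) %% 2147483629L))
    boot_rows[[i]] <- cbind(root_length_cm = f$profile$root_length_cm,
                            bs$summary, n_failed = bs$n_failed)
  }
  bootstrap_summary <- do.call(rbind, boot_rows)

  cp_rows <- lapply(ti_fits, function(f) {
    cp <- critical_points(f$params, root_length = f$profile$root_length_cm,
                          threshold = threshold, mvp_frac = mvp_frac,
                          basal_exclusion = basal_exclusion)
    data.frame(root_length_cm = f$profile$root_length_cm,
               t(cp$points))
  })
  cp_table <- do.call(rbind, cp_rows)
  rownames(cp_table) <- NULL

  unified <- fit_parameter_trends(ti_fits, breakpoint = breakpoint)

  volumes <- do.call(rbind, lapply(ti_fits, function(f) {
    v <- aerenchyma_volume(f$profile$root_length_cm, mean_diameter,
                           params = f$params)
    data.frame(root_length_cm = v$root_length_cm,
               mean_diameter_mm = v$mean_diameter_mm,
               volume_mm3 = v$volume_mm3)
  }))
  rownames(volumes) <- NULL

  utils::write.csv(comparison, outputs[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(bootstrap_summary, outputs[2], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cp_table, outputs[3], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(breakpoint = unified$breakpoint,
         short = unified$short, long = unified$long,
         slope_pvalues = unified$pvalues),
    outputs[4], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(volumes, outputs[5], row.names = FALSE, quote = FALSE)
  writeLines(c(
    sprintf("aerofit %s", as.character(utils::packageVersion("aerofit"))),
    sprintf("R %s", as.character(getRversion())),
    sprintf("seed: %d", base_seed),
    sprintf("n_boot: %d", n_boot),
    sprintf("input: %s", if (is.null(input)) "simulated" else input),
    sprintf("config_hash: %s", config_hash(config))
  ), outputs[6])

  invisible(list(comparison = comparison, bootstrap = bootstrap_summary,
                 critical_points = cp_table, unified = unified,
                 volumes = volumes, fits = ti_fits))
}
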