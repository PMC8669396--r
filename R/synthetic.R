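#' Configuration for the synthetic profile generator
#'
#' Encodes the sampling design of the source study: adventitious roots of
#' 2-16 cm, cross-sections every 0.5 cm from the apex, 12 replicate
#' measurements per position, additive Gaussian measurement noise (sd 1%), a
#' 1% detection floor below which no aerenchyma is scored, and exclusion of
#' the basal 1-cm segment from fitting. A multiplicative (constant-CV) noise
#' model is available as an alternative.
#'
#' @param root_lengths Root lengths to generate (cm).
#' @param step Sectioning interval (cm).
#' @param n_rep Replicates per position.
#' @param noise_sd Additive noise sd (%), or the CV when
#'   `noise_model = "multiplicative"`.
#' @param detection_threshold Detection floor (%): positions whose noiseless
#'   mean falls below it are scored 0.
#' @param basal_exclusion Basal segment excluded from fitting (cm).
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @param noise_model `"additive"` (default) or `"multiplicative"`.
#' @param coef [unified_coefficients()] supplying the true curve per length.
#' @return A `generator_config` list.
#' @export
generator_config <- function(root_lengths = 2:16, step = 0.5, n_rep = 12,
                             noise_sd = 1, detection_threshold = 1,
                             basal_exclusion = 1, seed = 1,
                             noise_model = c("additive", "multiplicative"),
                             coef = default_unified_coefficients()) {
  noise_model <- match.arg(noise_model)
  stopifnot(all(root_lengths > 0), step > 0, n_rep >= 1, noise_sd >= 0,
            detection_threshold >= 0, basal_exclusion >= 0,
            inherits(coef, "unified_coefficients"))
  structure(list(root_lengths = root_lengths, step = step, n_rep = n_rep,
                 noise_sd = noise_sd,
                 detection_threshold = detection_threshold,
                 basal_exclusion = basal_exclusion,
                 seed = as.integer(seed), noise_model = noise_model,
                 coef = coef),
            class = "generator_config")
}

# deterministic per-profile seed below 2^31
profile_seed <- function(config, L) {
  (abs(config$seed) * 1009L + as.integer(round(10 * L))) %% 2147483629L
}

#' Generate one synthetic aerenchyma profile
#'
#' Roots of 3 cm or shorter carry no aerenchyma and yield an all-zero
#' profile. For longer roots each replicate value is the unified-model
#' prediction at the position plus noise, clamped to `[0, 100]`; positions
#' whose noiseless mean is below the detection threshold are scored 0 (the
#' detection floor of the sectioning assay).
#'
#' @param L Root length (cm).
#' @param config A [generator_config()].
#' @return A [root_profile()].
#' @examples
#' pr <- generate_profile(8, generator_config(seed = 42))
#' profile_means(pr)
#' @export
generate_profile <- function(L, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"), L > 0)
  positions <- seq(0, L, by = config$step)
  n_pos <- length(positions)
  if (L <= 3) {
    values <- matrix(0, nrow = n_pos, ncol = config$n_rep)
  } else {
    truth <- predict_AR(L, positions, coef = config$coef)
    set.seed(profile_seed(config, L))
    noise <- if (config$noise_model == "additive") {
      matrix(stats::rnorm(n_pos * config$n_rep, sd = config$noise_sd),
             nrow = n_pos)
    } else {
      matrix(stats::rnorm(n_pos * config$n_rep), nrow = n_pos) *
        config$noise_sd * truth
    }
    values <- pmin(pmax(truth + noise, 0), 100)
    values[truth < config$detection_threshold, ] <- 0
  }
  root_profile(L, positions, values,
               basal_exclusion_cm = config$basal_exclusion)
}

#' Generate the full synthetic dataset
#'
#' One profile per configured root length; optionally written to `dir` as a
#' single long-format CSV (`profiles.csv`, schema of [read_profiles_csv()])
#' plus a `manifest.csv` recording the seed and a hash of the configuration,
#' so that re-running with the same config reproduces byte-identical files.
#'
#' @param config A [generator_config()].
#' @param dir Optional output directory.
#' @param overwrite Allow overwriting existing output files.
#' @return A named list of [root_profile()] objects (invisibly when writing
#'   to `dir`), with the manifest as attribute `"manifest"`.
#' @export
generate_dataset <- function(config = generator_config(), dir = NULL,
                             overwrite = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  profiles <- lapply(config$root_lengths, generate_profile, config = config)
  names(profiles) <- sprintf("L%g", config$root_lengths)
  manifest <- data.frame(
    seed = config$seed,
    n_profiles = length(profiles),
    step = config$step, n_rep = config$n_rep,
    noise_sd = config$noise_sd, noise_model = config$noise_model,
    detection_threshold = config$detection_threshold,
    basal_exclusion = config$basal_exclusion,
    config_hash = config_hash(config)
  )
  attr(profiles, "manifest") <- manifest
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, c("profiles.csv", "manifest.csv"))
    if (!overwrite && any(file.exists(paths))) {
      stop("output files already exist in ", dir,
           " (use overwrite = TRUE)", call. = FALSE)
    }
    write_profiles_csv(profiles, paths[1])
    utils::write.csv(manifest, paths[2], row.names = FALSE, quote = FALSE)
    return(invisible(profiles))
  }
  profiles
}

# polynomial rolling hash of the deparsed configuration (hex string);
# stable across runs of the same R version
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
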