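#' Construct a root aerenchyma profile
#'
#' A `root_profile` holds one root's measurements: its length, the positions
#' of the cross-sections (distances from the apex, cm), and a matrix of
#' replicate aerenchyma percentages (one row per position, one column per
#' replicate). The basal segment nearest the shoot (default 1 cm), where
#' measured aerenchyma dips below the sigmoid trend, is flagged for exclusion
#' from fitting.
#'
#' @param root_length_cm Root length (cm).
#' @param positions Strictly increasing distances from the apex (cm), all in
#'   `[0, root_length_cm]`. Defaults to a 0.5-cm sectioning grid.
#' @param values Matrix of aerenchyma percentages, `length(positions)` rows by
#'   `n_rep` columns (a vector is treated as a single replicate). All values
#'   must lie in `[0, 100]`.
#' @param basal_exclusion_cm Length of the basal segment excluded from
#'   fitting (cm, default 1).
#' @return An object of class `root_profile`.
#' @examples
#' pr <- root_profile(8, seq(0, 8, by = 0.5),
#'                    growth_curve("ti_gompertz",
#'                                 c(A = 33.34, B = 0.751, C = 2.824),
#'                                 seq(0, 8, by = 0.5)))
#' print(pr)
#' @export
root_profile <- function(root_length_cm, positions = seq(0, root_length_cm, by = 0.5),
                         values, basal_exclusion_cm = 1) {
  stopifnot(is.numeric(root_length_cm), length(root_length_cm) == 1L,
            root_length_cm > 0)
  positions <- as.numeric(positions)
  if (any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (any(positions < 0) || any(positions > root_length_cm + 1e-9)) {
    stop("positions must lie within [0, root_length_cm]", call. = FALSE)
  }
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  if (nrow(values) != length(positions)) {
    stop("values must have one row per position", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0) || any(values > 100)) {
    stop("aerenchyma percentages must be finite and within [0, 100]",
         call. = FALSE)
  }
  positions <- unname(positions)
  dimnames(values) <- NULL
  stopifnot(basal_exclusion_cm >= 0)
  structure(
    list(root_length_cm = root_length_cm,
         positions = positions,
         values = values,
         basal_exclusion_cm = basal_exclusion_cm),
    class = "root_profile"
  )
}

#' @export
print.root_profile <- function(x, ...) {
  cat(sprintf("Root aerenchyma profile: length %.1f cm, %d positions, %d replicate(s)\n",
              x$root_length_cm, length(x$positions), ncol(x$values)))
  m <- profile_means(x, fitting_only = FALSE)
  cat(sprintf("  positions %.1f-%.1f cm; mean aerenchyma %.2f-%.2f%%\n",
              min(x$positions), max(x$positions), min(m$mean), max(m$mean)))
  cat(sprintf("  basal exclusion: %.1f cm (%d positions used for fitting)\n",
              x$basal_exclusion_cm, sum(fitting_index(x))))
  invisible(x)
}

# logical index of positions retained for fitting (basal segment excluded)
fitting_index <- function(profile) {
  profile$positions <= profile$root_length_cm - profile$basal_exclusion_cm + 1e-9
}

#' Per-position mean aerenchyma percentages
#'
#' @param profile A [root_profile()].
#' @param fitting_only If `TRUE` (default), restrict to positions retained
#'   after basal exclusion.
#' @return A data frame with columns `position` and `mean`.
#' @export
profile_means <- function(profile, fitting_only = TRUE) {
  stopifnot(inherits(profile, "root_profile"))
  keep <- if (fitting_only) fitting_index(profile) else rep(TRUE, length(profile$positions))
  data.frame(position = profile$positions[keep],
             mean = rowMeans(profile$values[keep, , drop = FALSE]))
}

#' Read and write profiles in the long CSV exchange format
#'
#' The exchange schema has one row per (root, position, replicate) with
#' columns `root_length_cm`, `position_cm`, `replicate_id`, `aerenchyma_pct`
#' (UTF-8, header row, dot decimal).
#'
#' @param path CSV file path.
#' @param basal_exclusion_cm Basal exclusion applied to each profile (cm).
#' @return `read_profiles_csv()`: a named list of [root_profile()] objects,
#'   one per root length. `write_profiles_csv()`: the path, invisibly.
#' @export
read_profiles_csv <- function(path, basal_exclusion_cm = 1) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("input file is empty: ", path, call. = FALSE)
  need <- c("root_length_cm", "position_cm", "replicate_id", "aerenchyma_pct")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("root_length_cm", "position_cm", "aerenchyma_pct")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("malformed value in column ", col, " at data row ", bad[1],
           call. = FALSE)
    }
    df[[col]] <- v
  }
  out <- lapply(split(df, df$root_length_cm), function(d) {
    wide <- stats::reshape(
      d[c("position_cm", "replicate_id", "aerenchyma_pct")],
      idvar = "position_cm", timevar = "replicate_id", direction = "wide")
    wide <- wide[order(wide$position_cm), , drop = FALSE]
    root_profile(d$root_length_cm[1], wide$position_cm,
                 as.matrix(wide[, -1, drop = FALSE]),
                 basal_exclusion_cm = basal_exclusion_cm)
  })
  names(out) <- sprintf("L%s", names(out))
  out
}

#' @param profiles A list of [root_profile()] objects.
#' @rdname read_profiles_csv
#' @export
write_profiles_csv <- function(profiles, path) {
  if (inherits(profiles, "root_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    n_rep <- ncol(p$values)
    data.frame(
      root_length_cm = p$root_length_cm,
      position_cm = rep(p$positions, times = n_rep),
      replicate_id = rep(seq_len(n_rep), each = length(p$positions)),
      aerenchyma_pct = as.vector(p$values)
    )
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
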