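#' Read observer calibration pairs from CSV
#'
#' Calibration pairs are double counts of the same easily delimited areas:
#' one at the survey magnification (20x, "visual units") and one at higher
#' magnification (60x) or a true count where the area is accessible.
#'
#' @param path CSV with header
#'   `area_id,low_mag_count,high_mag_count[,observer_id][,year]`.
#' @return A tibble with those columns.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Calibration file not found: ", path),
          class = "cliffcensus_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("area_id", "low_mag_count", "high_mag_count"),
                          names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "cliffcensus_format_error")
  }
  raw
}

validate_pairs <- function(pairs, drop_zero_low = FALSE) {
  if (!is.data.frame(pairs)) {
    abort("`pairs` must be a data frame.", class = "cliffcensus_format_error")
  }
  missing_cols <- setdiff(c("low_mag_count", "high_mag_count"), names(pairs))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "cliffcensus_format_error")
  }
  pairs <- tibble::as_tibble(pairs)
  if (!"area_id" %in% names(pairs)) pairs$area_id <- as.character(seq_len(nrow(pairs)))
  ids <- as.character(pairs$area_id)
  check_counts(pairs$low_mag_count, "low_mag_count", ids)
  check_counts(pairs$high_mag_count, "high_mag_count", ids)
  if (any(pairs$high_mag_count < 1)) {
    bad <- ids[pairs$high_mag_count < 1]
    abort(paste0("high_mag_count must be >= 1; offending areas: ",
                 paste(bad, collapse = ", ")),
          class = "cliffcensus_validation_error")
  }
  zero <- pairs$low_mag_count == 0
  if (any(zero)) {
    if (drop_zero_low) {
      warn(paste0("Dropping ", sum(zero),
                  " pair(s) with zero low-magnification count: ",
                  paste(ids[zero], collapse = ", ")))
      pairs <- pairs[!zero, , drop = FALSE]
    } else {
      abort(paste0("low_mag_count is zero (ratio undefined) for areas: ",
                   paste(ids[zero], collapse = ", ")),
            class = "cliffcensus_validation_error")
    }
  }
  pairs
}

#' Per-area correction ratios
#'
#' The ratio `high_mag_count / low_mag_count` is the factor that converts
#' visual units into individuals for one calibration area.
#'
#' @param pairs Data frame of paired counts (see [read_calibration()]).
#' @param drop_zero_low Drop pairs with a zero low-magnification count with a
#'   warning instead of raising an error. Useful for batch runs.
#' @return A tibble with `area_id` and `ratio`.
#' @export
compute_ratios <- function(pairs, drop_zero_low = FALSE) {
  pairs <- validate_pairs(pairs, drop_zero_low = drop_zero_low)
  tibble::tibble(area_id = as.character(pairs$area_id),
                 ratio = pairs$high_mag_count / pairs$low_mag_count)
}

#' Shapiro-Wilk normality check for correction ratios
#'
#' The CF is a mean of ratios, so the ratios should be compatible with a
#' normal distribution before averaging.
#'
#' @param ratios Numeric vector of ratios (n >= 3).
#' @param alpha Significance level; the check passes when `p >= alpha`.
#' @return A list with `p_value`, `pass` and `degenerate` (all ratios equal,
#'   in which case no evidence against normality is computable and the check
#'   passes with a warning).
#' @export
test_normality <- function(ratios, alpha = 0.05) {
  ratios <- as.numeric(ratios)
  if (length(ratios) < 3) {
    abort("Need at least 3 ratios for a normality test.",
          class = "cliffcensus_insufficient_data_error")
  }
  if (sd(ratios) == 0) {
    warn("All ratios identical: normality not testable (zero variance); passing.")
    return(list(p_value = NA_real_, pass = TRUE, degenerate = TRUE))
  }
  p <- shapiro.test(ratios)$p.value
  list(p_value = p, pass = p >= alpha, degenerate = FALSE)
}

#' Estimate an observer correction factor
#'
#' The correction factor (CF) is the arithmetic mean of per-area ratios
#' between the precise count (high magnification or true count) and the
#' visual-unit count. Multiplying per-cell visual units by the CF converts
#' them into estimated individuals. CFs are observer- and year-specific: the
#' calibration must be repeated for each observer and sampling year.
#'
#' Recommended practice is 30-40 calibration areas; fewer pairs or a failed
#' normality check produce warnings, not errors, and the mean is still used.
#'
#' @inheritParams compute_ratios
#' @param alpha Significance level for the Shapiro-Wilk normality check.
#' @param observer_id,year Optional labels stored with the CF; applying a CF
#'   to data from a different observer/year should be done knowingly.
#' @param trim Trimming proportion for an optional trimmed mean (default 0,
#'   the plain mean).
#' @return An object of class `correction_factor`: a list with `mean_ratio`
#'   (the CF), `reciprocal_ratio` (its inverse, the 20x/60x orientation,
#'   reported for traceability), `sd_ratio`, `n_pairs`, `normality_p`,
#'   `observer_id`, `year` and accumulated `warnings`.
#' @examples
#' pairs <- data.frame(area_id = 1:2,
#'                     low_mag_count = c(10, 10), high_mag_count = c(20, 10))
#' estimate_cf(pairs)$mean_ratio  # 1.5
#' @export
estimate_cf <- function(pairs, alpha = 0.05, observer_id = NA_character_,
                        year = NA_integer_, drop_zero_low = FALSE, trim = 0) {
  ratios_df <- compute_ratios(pairs, drop_zero_low = drop_zero_low)
  ratios <- ratios_df$ratio
  n <- length(ratios)
  if (n < 2) {
    abort("Need at least 2 calibration pairs to estimate a CF.",
          class = "cliffcensus_insufficient_data_error")
  }
  warnings <- character()
  if (n < 30) {
    msg <- sprintf("Only %d calibration pairs; 30-40 are recommended.", n)
    warn(msg)
    warnings <- c(warnings, msg)
  }
  normality_p <- NA_real_
  if (n >= 3) {
    if (sd(ratios) == 0) {
      msg <- "All ratios identical: normality not testable (zero variance)."
      warn(msg)
      warnings <- c(warnings, msg)
      norm <- list(p_value = NA_real_, pass = TRUE, degenerate = TRUE)
    } else {
      norm <- test_normality(ratios, alpha = alpha)
    }
    normality_p <- norm$p_value
    if (!norm$degenerate && !norm$pass) {
      msg <- sprintf(
        "Ratios fail the normality check (Shapiro-Wilk p = %.4g < %.3g); the mean is still used.",
        norm$p_value, alpha)
      warn(msg)
      warnings <- c(warnings, msg)
    }
  }
  structure(list(
    mean_ratio = mean(ratios, trim = trim),
    reciprocal_ratio = 1 / mean(ratios, trim = trim),
    sd_ratio = sd(ratios),
    n_pairs = n,
    normality_p = normality_p,
    alpha = alpha,
    observer_id = observer_id,
    year = year,
    trim = trim,
    ratios = ratios,
    warnings = warnings
  ), class = "correction_factor")
}

cf_mean <- function(cf) {
  if (is.null(cf)) return(1)
  if (inherits(cf, "correction_factor")) return(cf$mean_ratio)
  if (is.numeric(cf) && length(cf) == 1 && cf > 0) return(as.numeric(cf))
  abort("`cf` must be a correction_factor object or a single positive number.",
        class = "cliffcensus_validation_error")
}

#' Apply a correction factor to a census
#'
#' Adds a `corrected_units` column: `visual_units * CF` for every cell. Raw
#' visual units are never overwritten.
#'
#' @param census A census data frame.
#' @param cf A [correction_factor] object or a single positive number.
#' @param observer_id,year Optional expected labels; a mismatch with the CF's
#'   labels produces a warning.
#' @return The census tibble with an added `corrected_units` column.
#' @export
apply_cf <- function(census, cf, observer_id = NULL, year = NULL) {
  census <- validate_census(census)
  m <- cf_mean(cf)
  if (inherits(cf, "correction_factor")) {
    if (!is.null(observer_id) && !is.na(cf$observer_id) &&
        !identical(observer_id, cf$observer_id)) {
      warn(sprintf("CF was calibrated for observer '%s' but applied for '%s'.",
                   cf$observer_id, observer_id))
    }
    if (!is.null(year) && !is.na(cf$year) && !identical(as.integer(year),
                                                        as.integer(cf$year))) {
      warn(sprintf("CF was calibrated for year %s but applied for year %s.",
                   cf$year, year))
    }
  }
  census$corrected_units <- census$visual_units * m
  census
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("<correction_factor> CF = %.4f (sd %.4f, n = %d)\n",
              x$mean_ratio, x$sd_ratio, x$n_pairs))
  cat(sprintf("  reciprocal (20x/60x orientation): %.4f\n", x$reciprocal_ratio))
  if (!is.na(x$normality_p)) {
    cat(sprintf("  Shapiro-Wilk p = %.4g\n", x$normality_p))
  }
  if (!is.na(x$observer_id) || !is.na(x$year)) {
    cat(sprintf("  observer: %s, year: %s\n", x$observer_id, x$year))
  }
  invisible(x)
}

#' Tidy a correction factor
#'
#' @param x A `correction_factor` object.
#' @param ... Unused.
#' @return A one-row tibble with the CF estimate and its standard error.
#' @export
tidy.correction_factor <- function(x, ...) {
  tibble::tibble(
    term = "correction_factor",
    estimate = x$mean_ratio,
    std.error = x$sd_ratio / sqrt(x$n_pairs),
    reciprocal = x$reciprocal_ratio
  )
}

#' One-row summary of a correction factor
#'
#' @inheritParams tidy.correction_factor
#' @return A one-row tibble.
#' @export
glance.correction_factor <- function(x, ...) {
  tibble::tibble(
    mean_ratio = x$mean_ratio,
    sd_ratio = x$sd_ratio,
    n_pairs = x$n_pairs,
    normality_p = x$normality_p,
    n_warnings = length(x$warnings)
  )
}

#' Write a correction-factor report as JSON
#'
#' @param cf A `correction_factor` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cf_report <- function(cf, path) {
  stopifnot(inherits(cf, "correction_factor"))
  report <- list(
    mean_ratio = cf$mean_ratio,
    reciprocal_ratio = cf$reciprocal_ratio,
    sd_ratio = cf$sd_ratio,
    n_pairs = cf$n_pairs,
    normality_p = cf$normality_p,
    observer_id = cf$observer_id,
    year = cf$year,
    warnings = cf$warnings
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
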