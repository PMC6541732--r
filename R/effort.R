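#' Subsampling design for the minimum-effort analysis
#'
#' The default design mirrors the reference protocol: sampling fractions
#' from 90% down to 5% in steps of 5%, 25 random subsamples per fraction,
#' and 10,000 bootstrap resamples for the simple-bootstrap interval.
#'
#' @param fractions Sampling proportions in (0, 1], strictly decreasing.
#' @param repetitions Random subsamples per fraction (>= 1).
#' @param bootstrap_B Bootstrap resamples for the SB interval (>= 100).
#' @param alpha Significance level for both interval methods.
#' @param seed Root seed; per-(fraction, replicate) streams are derived from
#'   it so every record is reproducible independently of execution order.
#' @return A list of class `effort_design`.
#' @export
effort_design <- function(fractions = seq(0.90, 0.05, by = -0.05),
                          repetitions = 25, bootstrap_B = 10000,
                          alpha = 0.05, seed = 1L) {
  if (any(fractions <= 0 | fractions > 1)) {
    abort("All fractions must lie in (0, 1].", class = "cliffcensus_validation_error")
  }
  if (is.unsorted(rev(fractions), strictly = TRUE)) {
    abort("Fractions must be strictly decreasing.",
          class = "cliffcensus_validation_error")
  }
  if (repetitions < 1) {
    abort("`repetitions` must be >= 1.", class = "cliffcensus_validation_error")
  }
  if (bootstrap_B < 100) {
    abort("`bootstrap_B` must be >= 100.", class = "cliffcensus_validation_error")
  }
  if (alpha <= 0 || alpha >= 0.5) {
    abort("`alpha` must lie in (0, 0.5).", class = "cliffcensus_validation_error")
  }
  structure(list(fractions = fractions, repetitions = as.integer(repetitions),
                 bootstrap_B = as.integer(bootstrap_B), alpha = alpha,
                 seed = as.integer(seed)),
            class = "effort_design")
}

# Deterministic per-record seed, < 2^31 for any 32-bit root seed.
derive_seed <- function(seed, fraction_index, replicate) {
  (abs(as.integer(seed)) %% 99991L) * 20000L + fraction_index * 200L + replicate
}

#' Draw a random subsample of grid cells
#'
#' Simple random sampling without replacement of
#' `round_half_up(fraction * n_included)` cells (at least 1): cells are
#' physical plots, so within one subsample each is censused at most once.
#'
#' @param census A census data frame.
#' @param fraction Sampling proportion in (0, 1].
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return The sampled rows of the census (included cells only), as a tibble.
#' @export
draw_subsample <- function(census, fraction, seed = NULL) {
  census <- validate_census(census)
  if (fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].", class = "cliffcensus_validation_error")
  }
  pool <- census[census$included, , drop = FALSE]
  n <- nrow(pool)
  if (n == 0) {
    abort("Census has no included cells.", class = "cliffcensus_validation_error")
  }
  m <- max(1L, round_half_up(fraction * n))
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, m, replace = FALSE)
  pool[sort(idx), , drop = FALSE]
}

#' Expand a subsample to a population-total estimate
#'
#' Fits the chosen family to the sampled counts by maximum likelihood and
#' expands: `total = n_total_cells * fitted mean * CF`. Because the fitted
#' mean equals the sample mean for all three families, this is the classical
#' expansion estimator; at sampling fraction 1 it reproduces the census
#' total exactly.
#'
#' @param sampled A census data frame of sampled cells or a numeric count
#'   vector.
#' @param n_total_cells Number of included cells in the full census.
#' @param family Count-model family for the fit.
#' @param cf Optional correction factor (object or number).
#' @return A single non-negative number.
#' @examples
#' estimate_total(rep(4.2, 10), n_total_cells = 147)  # 617.4
#' @export
estimate_total <- function(sampled, n_total_cells, family = "poisson", cf = NULL) {
  counts <- as_count_vector(sampled)
  if (length(counts) == 0) {
    abort("Subsample is empty.", class = "cliffcensus_insufficient_data_error")
  }
  if (all(counts == 0)) {
    warn("All sampled counts are zero; estimated total is 0.")
    return(0)
  }
  fit <- fit_count_distribution(counts, family)
  n_total_cells * distribution_mean(fit) * cf_mean(cf)
}

#' Maximum-likelihood confidence interval for the population total
#'
#' A log-normal approximation: the interval is
#' `T * exp(-z * s)` to `T * exp(z * s)` with `T` the expanded total and `s`
#' the delta-method standard error of `log T`. Since `T` is proportional to
#' the fitted mean, `s = SE(mean) / mean`, with `SE(mean)` obtained from the
#' fitted family's variance at the MLE (`sqrt(model variance / n)`), i.e.
#' from the observed information. The interval is asymmetric around `T` with
#' `high / T = T / low`, and collapses to `(0, 0)` with a warning when the
#' estimate is zero (undefined on the log scale).
#'
#' @inheritParams estimate_total
#' @param alpha Significance level (two-sided).
#' @return Named numeric vector `c(low, high)`, both positive for a positive
#'   estimate.
#' @export
ci_maximum_likelihood <- function(sampled, n_total_cells, family = "poisson",
                                  alpha = 0.05, cf = NULL) {
  counts <- as_count_vector(sampled)
  if (all(counts == 0)) {
    warn("Zero estimate: ML interval undefined on the log scale; returning (0, 0).")
    return(c(low = 0, high = 0))
  }
  fit <- fit_count_distribution(counts, family)
  m <- distribution_mean(fit)
  est <- n_total_cells * m * cf_mean(cf)
  s <- sqrt(distribution_variance(fit) / fit$n) / m
  z <- qnorm(1 - alpha / 2)
  c(low = est * exp(-z * s), high = est * exp(z * s))
}

#' Simple-bootstrap confidence interval for the population total
#'
#' Resamples the sampled cells with replacement `B` times, recomputes the
#' expanded total on each resample, and takes the `alpha/2` and
#' `1 - alpha/2` percentiles of the `B` totals. Since the fitted mean equals
#' the sample mean for every supported family, each resampled total is
#' `n_total_cells * resample mean * CF`, which is what is computed
#' (vectorised) here.
#'
#' @inheritParams ci_maximum_likelihood
#' @param B Number of bootstrap resamples (>= 100; the reference protocol
#'   uses 10,000).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Named numeric vector `c(low, high)`.
#' @export
ci_simple_bootstrap <- function(sampled, n_total_cells, family = "poisson",
                                alpha = 0.05, B = 10000, cf = NULL,
                                seed = NULL) {
  if (B < 100) {
    abort("`B` must be >= 100.", class = "cliffcensus_validation_error")
  }
  counts <- as_count_vector(sampled)
  n <- length(counts)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, n * B, replace = TRUE)
  boot_means <- colMeans(matrix(counts[idx], nrow = n, ncol = B))
  totals <- n_total_cells * boot_means * cf_mean(cf)
  q <- quantile(totals, probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  c(low = q[1], high = q[2])
}

#' Run the minimum-effort subsampling analysis
#'
#' For every sampling fraction and replicate in the design, draws a random
#' subsample of grid cells, expands it to a population-total estimate under
#' the chosen count model, and attaches maximum-likelihood and
#' simple-bootstrap confidence intervals. The best-fitting family is chosen
#' once on the full census (via AIC) and held fixed across subsamples unless
#' `refit_family = TRUE`.
#'
#' @param census A census data frame.
#' @param design An [effort_design()] (defaults mirror the reference
#'   protocol: fractions 0.90 to 0.05 by 0.05, 25 repetitions, B = 10,000).
#' @param family `"auto"` (select by AIC on the full census) or one of the
#'   supported family names.
#' @param cf Optional correction factor applied to estimates and to the
#'   census total stored alongside.
#' @param refit_family Re-select the family by AIC within every subsample
#'   instead of holding the full-census choice fixed.
#' @return A tibble of class `effort_records` with one row per (fraction,
#'   replicate): `fraction`, `replicate`, `n_cells`, `estimate`, `ml_low`,
#'   `ml_high`, `sb_low`, `sb_high`, `family`, `note`. The design, chosen
#'   family, CF mean and (corrected) census total travel as attributes.
#' @export
run_effort_analysis <- function(census, design = effort_design(),
                                family = "auto", cf = NULL,
                                refit_family = FALSE) {
  census <- validate_census(census)
  stopifnot(inherits(design, "effort_design"))
  pool <- census[census$included, , drop = FALSE]
  n_total <- nrow(pool)
  if (n_total == 0) {
    abort("Census has no included cells.", class = "cliffcensus_validation_error")
  }
  if (identical(family, "auto")) {
    cmp <- suppressWarnings(compare_count_models(census))
    family <- best_fit(cmp)$family
  } else {
    family <- match_family(family)
  }
  cfm <- cf_mean(cf)
  grid <- tidyr::expand_grid(
    fraction_index = seq_along(design$fractions),
    replicate = seq_len(design$repetitions)
  )
  records <- purrr::pmap(grid, function(fraction_index, replicate) {
    fraction <- design$fractions[fraction_index]
    sub_seed <- derive_seed(design$seed, fraction_index, replicate)
    note <- NA_character_
    res <- tryCatch({
      sampled <- draw_subsample(census, fraction, seed = sub_seed)
      counts <- sampled$visual_units
      fam <- family
      if (refit_family && !all(counts == 0)) {
        fam <- best_fit(suppressWarnings(compare_count_models(counts)))$family
      }
      est <- suppressWarnings(
        estimate_total(counts, n_total, family = fam, cf = cfm))
      ml <- suppressWarnings(
        ci_maximum_likelihood(counts, n_total, family = fam,
                              alpha = design$alpha, cf = cfm))
      sb <- ci_simple_bootstrap(counts, n_total, family = fam,
                                alpha = design$alpha, B = design$bootstrap_B,
                                cf = cfm)
      if (all(counts == 0)) note <- "all-zero subsample"
      tibble::tibble(fraction = fraction, replicate = replicate,
                     n_cells = nrow(sampled), estimate = est,
                     ml_low = ml[["low"]], ml_high = ml[["high"]],
                     sb_low = sb[["low"]], sb_high = sb[["high"]],
                     family = fam, note = note)
    }, error = function(e) {
      tibble::tibble(fraction = fraction, replicate = replicate,
                     n_cells = NA_integer_, estimate = NA_real_,
                     ml_low = NA_real_, ml_high = NA_real_,
                     sb_low = NA_real_, sb_high = NA_real_,
                     family = family, note = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(records)
  structure(out,
            design = design, family = family, cf_mean = cfm,
            census_total = total_count(census, cf = cfm),
            class = c("effort_records", class(tibble::tibble())))
}

#' Summarize a minimum-effort run per sampling fraction
#'
#' Aggregates the per-replicate records: mean estimate, mean/min/max CI
#' bounds and mean CI width per method, and the fraction of replicates whose
#' interval covers the full-census total. Recommends the interval method
#' with the smaller mean width (at `fraction_of_interest` when given,
#' otherwise averaged over all fractions), and the smallest sampling
#' fraction whose mean relative CI half-width stays within `hw_tol` and
#' whose coverage reaches `coverage_floor` under that method.
#'
#' @param records An `effort_records` tibble from [run_effort_analysis()].
#' @param census_total Reference total; defaults to the (CF-corrected)
#'   full-census total stored on `records`.
#' @param hw_tol Maximum acceptable mean relative CI half-width
#'   (default 0.15).
#' @param coverage_floor Minimum acceptable coverage of the census total
#'   (default 0.90).
#' @param fraction_of_interest Optional fraction at which the method
#'   recommendation is made.
#' @return An object of class `effort_summary`: list with `by_fraction`
#'   (a tibble), `recommended_method` (`"ML"` or `"SB"`),
#'   `recommended_fraction` (possibly `NA` if no fraction qualifies),
#'   `census_total`, `hw_tol`, `coverage_floor`.
#' @export
summarize_effort <- function(records, census_total = NULL, hw_tol = 0.15,
                             coverage_floor = 0.90,
                             fraction_of_interest = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  census_total <- census_total %||% attr(records, "census_total")
  if (is.null(census_total)) {
    abort("`census_total` must be supplied when records carry none.",
          class = "cliffcensus_validation_error")
  }
  ok <- !is.na(records$estimate)
  by_fraction <- records[ok, , drop = FALSE] |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_cells = mean(.data$n_cells),
      mean_estimate = mean(.data$estimate),
      ml_low_mean = mean(.data$ml_low), ml_low_min = min(.data$ml_low),
      ml_low_max = max(.data$ml_low),
      ml_high_mean = mean(.data$ml_high), ml_high_min = min(.data$ml_high),
      ml_high_max = max(.data$ml_high),
      sb_low_mean = mean(.data$sb_low), sb_low_min = min(.data$sb_low),
      sb_low_max = max(.data$sb_low),
      sb_high_mean = mean(.data$sb_high), sb_high_min = min(.data$sb_high),
      sb_high_max = max(.data$sb_high),
      ml_width_mean = mean(.data$ml_high - .data$ml_low),
      sb_width_mean = mean(.data$sb_high - .data$sb_low),
      ml_rel_halfwidth = mean((.data$ml_high - .data$ml_low) / 2 /
                                .data$estimate),
      sb_rel_halfwidth = mean((.data$sb_high - .data$sb_low) / 2 /
                                .data$estimate),
      ml_coverage = mean(.data$ml_low <= census_total &
                           census_total <= .data$ml_high),
      sb_coverage = mean(.data$sb_low <= census_total &
                           census_total <= .data$sb_high),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$fraction))

  if (is.null(fraction_of_interest)) {
    ml_w <- mean(by_fraction$ml_width_mean)
    sb_w <- mean(by_fraction$sb_width_mean)
  } else {
    row <- by_fraction[which.min(abs(by_fraction$fraction - fraction_of_interest)), ]
    ml_w <- row$ml_width_mean
    sb_w <- row$sb_width_mean
  }
  method <- if (ml_w <= sb_w) "ML" else "SB"
  rel_hw <- if (method == "ML") by_fraction$ml_rel_halfwidth else by_fraction$sb_rel_halfwidth
  cover <- if (method == "ML") by_fraction$ml_coverage else by_fraction$sb_coverage
  eligible <- by_fraction$fraction[rel_hw <= hw_tol & cover >= coverage_floor]
  structure(list(
    by_fraction = by_fraction,
    recommended_method = method,
    recommended_fraction = if (length(eligible)) min(eligible) else NA_real_,
    census_total = census_total,
    hw_tol = hw_tol,
    coverage_floor = coverage_floor
  ), class = "effort_summary")
}

#' @export
print.effort_summary <- function(x, ...) {
  cat(sprintf("<effort_summary> census total %.1f\n", x$census_total))
  cat(sprintf("  recommended method: %s; recommended fraction: %s\n",
              x$recommended_method,
              if (is.na(x$recommended_fraction)) "none qualifies"
              else sprintf("%.0f%%", 100 * x$recommended_fraction)))
  print(x$by_fraction[, c("fraction", "mean_estimate", "ml_width_mean",
                          "sb_width_mean", "ml_coverage", "sb_coverage")])
  invisible(x)
}

#' Tidy an effort summary
#'
#' @param x An `effort_summary` object.
#' @param ... Unused.
#' @return The per-fraction tibble.
#' @export
tidy.effort_summary <- function(x, ...) x$by_fraction

#' One-row summary of an effort analysis
#'
#' @inheritParams tidy.effort_summary
#' @return A one-row tibble with the recommendation.
#' @export
glance.effort_summary <- function(x, ...) {
  tibble::tibble(census_total = x$census_total,
                 recommended_method = x$recommended_method,
                 recommended_fraction = x$recommended_fraction,
                 hw_tol = x$hw_tol, coverage_floor = x$coverage_floor)
}

#' Write effort records to CSV
#'
#' @param records An `effort_records` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effort_records <- function(records, path) {
  out <- records[, c("fraction", "replicate", "n_cells", "estimate",
                     "ml_low", "ml_high", "sb_low", "sb_high")]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write an effort summary as JSON
#'
#' @param summary An `effort_summary` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effort_summary <- function(summary, path) {
  stopifnot(inherits(summary, "effort_summary"))
  payload <- list(
    census_total = summary$census_total,
    recommended_method = summary$recommended_method,
    recommended_fraction = summary$recommended_fraction,
    hw_tol = summary$hw_tol,
    coverage_floor = summary$coverage_floor,
    by_fraction = summary$by_fraction
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

effort_long <- function(records) {
  records |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(cols = c("ml_low", "ml_high", "sb_low", "sb_high"),
                        names_to = c("method", "bound"), names_sep = "_",
                        values_to = "value") |>
    dplyr::mutate(method = toupper(.data$method))
}

#' Boxplots of estimates and CI bounds per sampling fraction
#'
#' One panel per interval method, with boxplots of the lower and upper CI
#' bounds across replicates at each fraction and a red reference line at the
#' full-census total.
#'
#' @param object An `effort_records` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effort_records <- function(object, ...) {
  census_total <- attr(object, "census_total")
  long <- effort_long(object)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(100 * .data$fraction),
                               y = .data$value,
                               fill = .data$bound)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = census_total, colour = "red") +
    ggplot2::facet_wrap(~method, ncol = 1) +
    ggplot2::labs(x = "Cells sampled (%)", y = "Estimated population total",
                  fill = "CI bound") +
    ggplot2::theme_minimal()
}

#' Boxplots of the estimated totals per sampling fraction
#'
#' @param records An `effort_records` tibble.
#' @return A ggplot object with a red reference line at the census total.
#' @export
plot_effort_estimates <- function(records) {
  census_total <- attr(records, "census_total")
  ggplot2::ggplot(tibble::as_tibble(records),
                  ggplot2::aes(x = factor(100 * .data$fraction),
                               y = .data$estimate)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, linewidth = 0.3,
                          fill = "grey85") +
    ggplot2::geom_hline(yintercept = census_total, colour = "red") +
    ggplot2::labs(x = "Cells sampled (%)", y = "Estimated population total") +
    ggplot2::theme_minimal()
}

#' Detail view of the confidence intervals at one sampling fraction
#'
#' @param records An `effort_records` tibble.
#' @param fraction The fraction to display (e.g. 0.55).
#' @return A ggplot object.
#' @export
plot_effort_fraction <- function(records, fraction = 0.55) {
  census_total <- attr(records, "census_total")
  sub <- dplyr::filter(tibble::as_tibble(records),
                       abs(.data$fraction - !!fraction) < 1e-9)
  if (nrow(sub) == 0) {
    abort("No records at the requested fraction.",
          class = "cliffcensus_validation_error")
  }
  long <- effort_long(sub)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     fill = .data$bound)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = census_total, colour = "red") +
    ggplot2::labs(title = sprintf("CI at %.0f%% sampling", 100 * fraction),
                  x = NULL, y = "Estimated population total",
                  fill = "CI bound") +
    ggplot2::theme_minimal()
}

#' Render the effort figures to disk
#'
#' Writes three figures: CI bounds per fraction and method, estimate
#' boxplots per fraction, and the single-fraction detail view.
#'
#' @param records An `effort_records` tibble.
#' @param dir Output directory (must exist).
#' @param fraction Fraction for the detail view.
#' @param ext File extension: `"pdf"`, `"png"` or `"svg"`.
#' @return Character vector of files written, invisibly.
#' @export
render_effort_plots <- function(records, dir, fraction = 0.55, ext = "png") {
  if (nrow(records) == 0) {
    abort("No effort records to plot.", class = "cliffcensus_validation_error")
  }
  if (!dir.exists(dir)) {
    abort(paste0("Output directory does not exist: ", dir),
          class = "cliffcensus_io_error")
  }
  fraction <- if (any(abs(records$fraction - fraction) < 1e-9)) fraction
              else records$fraction[which.min(abs(records$fraction - fraction))]
  files <- file.path(dir, paste0(c("effort-ci", "effort-estimates",
                                   "effort-detail"), ".", ext))
  ggplot2::ggsave(files[1], autoplot.effort_records(records),
                  width = 9, height = 7, dpi = 150)
  ggplot2::ggsave(files[2], plot_effort_estimates(records),
                  width = 9, height = 5, dpi = 150)
  ggplot2::ggsave(files[3], plot_effort_fraction(records, fraction),
                  width = 6, height = 5, dpi = 150)
  invisible(files)
}
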