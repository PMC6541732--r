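#' Describe a synthetic cliff scenario
#'
#' Bundles the ground truth for a simulated cliff wall: grid size, the count
#' distribution of visual units per cell, the true observer correction
#' factor and its relative noise, and the number of calibration areas. The
#' defaults describe a realistic wall: 147 cells, clumped (negative
#' binomial) counts, an observer who sees two thirds of the individuals
#' (CF 1.5) with 10% relative noise, and 35 calibration areas (inside the
#' recommended 30-40 band).
#'
#' @param n_cells Number of grid cells (>= 10).
#' @param family Generating count family.
#' @param params Named list of family parameters (`lambda`; `prob`; or
#'   `size` and `mu`).
#' @param cf_true True correction factor (> 0).
#' @param cf_noise_sd Relative (multiplicative) noise SD of the observer's
#'   low-magnification counts.
#' @param n_calibration_pairs Number of calibration areas (>= 2).
#' @param calibration_mean Mean true count per calibration area.
#' @param seed Seed for reproducibility.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_cells = 147, family = "nbinom",
                               params = list(size = 1.5, mu = 4),
                               cf_true = 1.5, cf_noise_sd = 0.1,
                               n_calibration_pairs = 35,
                               calibration_mean = 20, seed = 1L) {
  family <- match_family(family)
  if (n_cells < 10) {
    abort("`n_cells` must be >= 10.", class = "cliffcensus_validation_error")
  }
  if (cf_true <= 0) {
    abort("`cf_true` must be positive.", class = "cliffcensus_validation_error")
  }
  if (cf_noise_sd < 0) {
    abort("`cf_noise_sd` must be non-negative.",
          class = "cliffcensus_validation_error")
  }
  if (n_calibration_pairs < 2) {
    abort("`n_calibration_pairs` must be >= 2.",
          class = "cliffcensus_validation_error")
  }
  needed <- switch(family, poisson = "lambda", geometric = "prob",
                   nbinom = c("size", "mu"))
  if (!all(needed %in% names(params))) {
    abort(paste0("Family '", family, "' needs parameter(s): ",
                 paste(needed, collapse = ", "), "."),
          class = "cliffcensus_validation_error")
  }
  structure(list(n_cells = as.integer(n_cells), family = family,
                 params = params, cf_true = cf_true,
                 cf_noise_sd = cf_noise_sd,
                 n_calibration_pairs = as.integer(n_calibration_pairs),
                 calibration_mean = calibration_mean,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Simulate a grid census with known ground truth
#'
#' Draws i.i.d. per-cell visual-unit counts from the scenario's family.
#' Two ground-truth totals are attached as attributes: `census_total`, the
#' realized sum of the generated counts (what an exhaustive census would
#' record), and `true_total`, the process-level expected total
#' `n_cells * E[count]` that the model-based interval methods target.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A [grid_census()] tibble with attributes `true_total`,
#'   `census_total` and `scenario`.
#' @export
simulate_census <- function(scenario = synthetic_scenario()) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  counts <- family_rfun(scenario$family)(scenario$n_cells, scenario$params)
  census <- grid_census(tibble::tibble(
    cell_id = sprintf("C%03d", seq_len(scenario$n_cells)),
    visual_units = counts
  ))
  attr(census, "true_total") <-
    scenario$n_cells * family_mean(scenario$family, scenario$params)
  attr(census, "census_total") <- sum(counts)
  attr(census, "scenario") <- scenario
  census
}

#' Simulate observer calibration pairs with known ground truth
#'
#' High-magnification (precise) counts are drawn from the scenario's family
#' shifted to `calibration_mean`; the low-magnification visual-unit count is
#' the precise count divided by the true CF with multiplicative Gaussian
#' noise, rounded, and floored at 1 (a floor hit is reported with a
#' warning). Estimating a CF on the output recovers `cf_true` up to rounding
#' and noise.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A tibble of calibration pairs with columns `area_id`,
#'   `low_mag_count`, `high_mag_count`, and attribute `cf_true`.
#' @export
simulate_calibration_pairs <- function(scenario = synthetic_scenario()) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed + 1L)
  n <- scenario$n_calibration_pairs
  # Poisson around the calibration mean: areas are chosen to be easily
  # delimited, so clumping matters less than on whole cells
  high <- rpois(n, scenario$calibration_mean)
  high <- pmax(high, 1L)
  noise <- 1 + rnorm(n, 0, scenario$cf_noise_sd)
  low <- round_half_up(high / scenario$cf_true * noise)
  if (any(low < 1)) {
    warn(sprintf("%d low-magnification count(s) clipped to 1.", sum(low < 1)))
    low <- pmax(low, 1)
  }
  structure(tibble::tibble(
    area_id = sprintf("A%02d", seq_len(n)),
    low_mag_count = as.integer(low),
    high_mag_count = as.integer(high)
  ), cf_true = scenario$cf_true)
}
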