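test_that("subsamples are SRSWOR with round-half-up sizes and deterministic", {
  cen <- toy_census(counts = rep(1L, 100))
  s55 <- draw_subsample(cen, 0.55, seed = 4)
  expect_equal(nrow(s55), 55)
  expect_equal(anyDuplicated(s55$cell_id), 0)

  expect_equal(nrow(draw_subsample(cen, 1.0, seed = 4)), 100)
  expect_identical(draw_subsample(cen, 0.3, seed = 9),
                   draw_subsample(cen, 0.3, seed = 9))

  # round-half-up with a floor of one cell
  cen9 <- toy_census(counts = rep(1L, 9))
  expect_equal(nrow(draw_subsample(cen9, 0.5, seed = 1)), 5)   # 4.5 -> 5
  expect_equal(nrow(draw_subsample(cen9, 0.01, seed = 1)), 1)  # floor

  # excluded cells never enter the pool
  cen_ex <- exclude_edge_cells(cen, paste0("A", 1:50))
  expect_equal(nrow(draw_subsample(cen_ex, 1.0, seed = 2)), 50)
  expect_error(draw_subsample(toy_census(included = FALSE), 0.5),
               class = "cliffcensus_validation_error")
  expect_error(draw_subsample(cen, 1.2),
               class = "cliffcensus_validation_error")
})

test_that("the expansion estimator scales the fitted mean to the full grid", {
  x42 <- c(4, 4, 4, 5, 4, 4, 4, 5, 4, 4)  # subsample mean 4.2
  expect_equal(estimate_total(x42, n_total_cells = 147), 617.4)
  expect_equal(estimate_total(c(5, 0, 12), 3), 17)
  expect_equal(estimate_total(c(5, 0, 12), 3, cf = 2), 34)
  expect_warning(z <- estimate_total(rep(0L, 5), 100, "poisson"), "zero")
  expect_equal(z, 0)

  # at fraction 1 the estimate is the census total, for all three families
  set.seed(37)
  for (i in 1:5) {
    x <- rnbinom(60, size = 1.5, mu = 4)
    for (fam in c("poisson", "geometric", "nbinom")) {
      if (all(x == 0)) next
      expect_equal(estimate_total(x, length(x), fam), sum(x))
    }
  }
})

test_that("ML interval is log-symmetric and handles degenerate input", {
  set.seed(43)
  x <- rpois(80, 6)
  ci <- ci_maximum_likelihood(x, 200, "poisson", alpha = 0.05)
  est <- estimate_total(x, 200, "poisson")
  expect_lt(ci[["low"]], est)
  expect_gt(ci[["high"]], est)
  expect_equal(ci[["high"]] / est, est / ci[["low"]])

  # z quantile: width on the log scale is 2 * 1.96 * s
  fit <- fit_count_distribution(x, "poisson")
  s <- sqrt(distribution_variance(fit) / fit$n) / distribution_mean(fit)
  expect_equal(log(ci[["high"]] / ci[["low"]]), 2 * qnorm(0.975) * s)

  expect_warning(ci0 <- ci_maximum_likelihood(rep(0L, 5), 100), "log scale")
  expect_equal(unname(ci0), c(0, 0))
})

test_that("simple-bootstrap interval is a percentile interval of resampled totals", {
  # constant counts resample to a zero-width interval at the estimate
  ci <- ci_simple_bootstrap(rep(4L, 20), 100, "poisson", B = 500, seed = 1)
  expect_equal(unname(ci), c(400, 400))

  set.seed(47)
  x <- rpois(60, 6)
  est <- estimate_total(x, 150, "poisson")
  ci1 <- ci_simple_bootstrap(x, 150, "poisson", B = 2000, seed = 5)
  expect_lte(ci1[["low"]], est)
  expect_gte(ci1[["high"]], est)
  expect_identical(ci1, ci_simple_bootstrap(x, 150, "poisson", B = 2000,
                                            seed = 5))
  expect_error(ci_simple_bootstrap(x, 150, B = 50),
               class = "cliffcensus_validation_error")

  # at large B the interval stabilizes across seeds (< 2% relative)
  a <- ci_simple_bootstrap(x, 150, "poisson", B = 10000, seed = 11)
  b <- ci_simple_bootstrap(x, 150, "poisson", B = 10000, seed = 12)
  expect_lt(abs(a[["low"]] - b[["low"]]) / b[["low"]], 0.02)
  expect_lt(abs(a[["high"]] - b[["high"]]) / b[["high"]], 0.02)
})

test_that("effort design defaults mirror the reference protocol and validate", {
  des <- effort_design()
  expect_equal(des$fractions, seq(0.90, 0.05, by = -0.05))
  expect_length(des$fractions, 18)
  expect_equal(des$repetitions, 25L)
  expect_equal(des$bootstrap_B, 10000L)
  expect_equal(des$alpha, 0.05)
  expect_error(effort_design(fractions = c(0.5, 0.9)),
               class = "cliffcensus_validation_error")
  expect_error(effort_design(fractions = c(0.9, 0)),
               class = "cliffcensus_validation_error")
  expect_error(effort_design(bootstrap_B = 10),
               class = "cliffcensus_validation_error")
  expect_error(effort_design(alpha = 0.6),
               class = "cliffcensus_validation_error")
})

test_that("run_effort_analysis produces one record per fraction x replicate", {
  cen <- simulate_census(synthetic_scenario(n_cells = 60, family = "poisson",
                                            params = list(lambda = 5),
                                            seed = 2))
  des <- effort_design(fractions = c(0.8, 0.4, 0.2), repetitions = 4,
                       bootstrap_B = 200, seed = 10)
  rec <- run_effort_analysis(cen, des, family = "poisson")
  expect_equal(nrow(rec), 12)
  expect_equal(unique(rec$family), "poisson")
  expect_true(all(rec$ml_low <= rec$estimate & rec$estimate <= rec$ml_high))
  expect_true(all(rec$sb_low <= rec$estimate + 1e-9 &
                    rec$estimate <= rec$sb_high + 1e-9))
  expect_equal(attr(rec, "census_total"), total_count(cen))

  # degenerate design: one replicate at full sampling reproduces the total
  rec1 <- run_effort_analysis(cen, effort_design(fractions = 1.0,
                                                 repetitions = 1,
                                                 bootstrap_B = 200, seed = 1),
                              family = "nbinom")
  expect_equal(rec1$estimate, total_count(cen))

  # family = "auto" picks the AIC winner on the full census
  rec_auto <- run_effort_analysis(cen, des, family = "auto")
  cmp <- suppressWarnings(compare_count_models(cen))
  expect_equal(attr(rec_auto, "family"), cmp$family[1])

  # CF scales every estimate linearly
  rec_cf <- run_effort_analysis(cen, des, family = "poisson", cf = 2)
  expect_equal(rec_cf$estimate, 2 * rec$estimate)
})

test_that("summarize_effort aggregates, covers and recommends", {
  cen <- simulate_census(synthetic_scenario(n_cells = 80, family = "poisson",
                                            params = list(lambda = 6),
                                            seed = 5))
  des <- effort_design(fractions = c(0.9, 0.5, 0.2), repetitions = 6,
                       bootstrap_B = 300, seed = 3)
  rec <- run_effort_analysis(cen, des, family = "poisson")
  smry <- summarize_effort(rec)
  expect_equal(nrow(smry$by_fraction), 3)
  expect_true(all(smry$by_fraction$ml_coverage >= 0 &
                    smry$by_fraction$ml_coverage <= 1))
  expect_true(all(smry$by_fraction$ml_width_mean >= 0))
  expect_true(all(smry$by_fraction$ml_low_min <= smry$by_fraction$ml_low_mean &
                    smry$by_fraction$ml_low_mean <= smry$by_fraction$ml_low_max))
  expect_true(smry$recommended_method %in% c("ML", "SB"))
  expect_equal(glance(smry)$census_total, total_count(cen))
  expect_equal(tidy(smry), smry$by_fraction)

  # records from a single fraction with identical CIs reproduce them exactly
  const <- tibble::tibble(fraction = 0.5, replicate = 1:4, n_cells = 10L,
                          estimate = 100, ml_low = 90, ml_high = 110,
                          sb_low = 92, sb_high = 108, family = "poisson",
                          note = NA_character_)
  s2 <- summarize_effort(const, census_total = 100)
  expect_equal(s2$by_fraction$ml_low_mean, 90)
  expect_equal(s2$by_fraction$ml_low_min, 90)
  expect_equal(s2$by_fraction$sb_width_mean, 16)
  expect_equal(s2$by_fraction$ml_coverage, 1)

  # the method choice flips when one method's widths are inflated
  wide_ml <- dplyr::mutate(const, ml_low = 0, ml_high = 500)
  expect_equal(summarize_effort(wide_ml, census_total = 100)$recommended_method,
               "SB")
  wide_sb <- dplyr::mutate(const, sb_low = 0, sb_high = 500)
  expect_equal(summarize_effort(wide_sb, census_total = 100)$recommended_method,
               "ML")
})

test_that("effort records export, plot and render", {
  cen <- simulate_census(synthetic_scenario(n_cells = 50, family = "poisson",
                                            params = list(lambda = 4),
                                            seed = 8))
  des <- effort_design(fractions = c(0.8, 0.55, 0.3), repetitions = 3,
                       bootstrap_B = 200, seed = 2)
  rec <- run_effort_analysis(cen, des, family = "poisson")

  csv <- withr::local_tempfile(fileext = ".csv")
  write_effort_records(rec, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$estimate, rec$estimate)

  js <- withr::local_tempfile(fileext = ".json")
  write_effort_summary(summarize_effort(rec), js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$census_total, total_count(cen))

  expect_s3_class(autoplot(rec), "ggplot")
  expect_s3_class(plot_effort_estimates(rec), "ggplot")
  expect_s3_class(plot_effort_fraction(rec, 0.55), "ggplot")
  dir <- withr::local_tempdir()
  files <- render_effort_plots(rec, dir, fraction = 0.55, ext = "pdf")
  expect_length(files, 3)
  expect_true(all(file.exists(files)))
  expect_true(all(file.size(files) > 0))
})
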