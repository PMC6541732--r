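test_that("compute_ratios divides precise by visual-unit counts", {
  pairs <- tibble::tibble(area_id = c("a", "b"),
                          low_mag_count = c(10L, 5L),
                          high_mag_count = c(20L, 10L))
  expect_equal(compute_ratios(pairs)$ratio, c(2, 2))
  expect_equal(compute_ratios(tibble::tibble(low_mag_count = 7,
                                             high_mag_count = 7))$ratio, 1)

  zero <- tibble::tibble(area_id = "z", low_mag_count = 0L,
                         high_mag_count = 3L)
  expect_error(compute_ratios(zero), "z",
               class = "cliffcensus_validation_error")
  expect_warning(out <- compute_ratios(dplyr::bind_rows(pairs, zero),
                                       drop_zero_low = TRUE), "z")
  expect_equal(nrow(out), 2)
})

test_that("normality check behaves at its nominal level and on edge cases", {
  # normal ratios pass at alpha = 0.05 in >= 90% of seeds
  pass <- vapply(1:100, function(s) {
    set.seed(s)
    test_normality(rnorm(35, 1.5, 0.1))$pass
  }, logical(1))
  expect_gte(mean(pass), 0.90)

  # heavily skewed ratios fail in the majority of seeds
  fail <- vapply(1:100, function(s) {
    set.seed(s)
    !test_normality(rexp(35))$pass
  }, logical(1))
  expect_gt(mean(fail), 0.5)

  expect_warning(res <- test_normality(rep(1.3, 10)), "identical")
  expect_true(res$pass)
  expect_true(res$degenerate)
  expect_error(test_normality(c(1, 2)),
               class = "cliffcensus_insufficient_data_error")
})

test_that("estimate_cf averages ratios and records diagnostics", {
  const <- tibble::tibble(area_id = 1:35, low_mag_count = 10L,
                          high_mag_count = 15L)
  expect_warning(estimate_cf(const), "identical")
  cf <- suppressWarnings(estimate_cf(const))
  expect_equal(cf$mean_ratio, 1.5)
  expect_equal(cf$sd_ratio, 0)
  expect_equal(cf$n_pairs, 35)
  expect_equal(cf$reciprocal_ratio, 1 / 1.5)

  two <- tibble::tibble(area_id = 1:2, low_mag_count = c(10L, 10L),
                        high_mag_count = c(20L, 10L))
  cf2 <- suppressWarnings(estimate_cf(two))
  expect_equal(cf2$mean_ratio, 1.5)
  expect_match(cf2$warnings, "recommended", all = FALSE)

  expect_error(estimate_cf(two[1, ]),
               class = "cliffcensus_insufficient_data_error")

  # permutation invariance
  set.seed(5)
  pairs <- tibble::tibble(area_id = 1:35,
                          low_mag_count = rpois(35, 12) + 1L,
                          high_mag_count = rpois(35, 18) + 1L)
  a <- suppressWarnings(estimate_cf(pairs))
  b <- suppressWarnings(estimate_cf(pairs[sample.int(35), ]))
  expect_equal(a$mean_ratio, b$mean_ratio)
  expect_equal(a$sd_ratio, b$sd_ratio)

  # pairs with low = high give CF exactly 1
  eq <- tibble::tibble(area_id = 1:35, low_mag_count = rpois(35, 20) + 1L)
  eq$high_mag_count <- eq$low_mag_count
  expect_equal(suppressWarnings(estimate_cf(eq))$mean_ratio, 1)
})

test_that("estimate_cf recovers a known factor from noisy synthetic pairs", {
  set.seed(21)
  high <- rpois(35, 30) + 1L
  low <- pmax(1, round(high / 1.8 * (1 + rnorm(35, 0, 0.05))))
  cf <- suppressWarnings(estimate_cf(tibble::tibble(
    area_id = 1:35, low_mag_count = low, high_mag_count = high)))
  se <- cf$sd_ratio / sqrt(cf$n_pairs)
  expect_lt(abs(cf$mean_ratio - 1.8), 3 * se)
})

test_that("apply_cf scales included counts without touching raw units", {
  cen <- toy_census(counts = c(7L, 2L, 4L))
  out <- apply_cf(cen, 1.5)
  expect_equal(out$corrected_units, c(10.5, 3, 6))
  expect_identical(out$visual_units, cen$visual_units)
  expect_equal(apply_cf(cen, 1)$corrected_units, as.numeric(cen$visual_units))

  # linearity: corrected total = CF x raw total
  expect_equal(total_count(cen, cf = 2), 2 * total_count(cen))

  cf <- suppressWarnings(estimate_cf(tibble::tibble(
    area_id = 1:5, low_mag_count = 10L, high_mag_count = 20L),
    observer_id = "obs1", year = 2018L))
  expect_warning(apply_cf(cen, cf, observer_id = "obs2"), "observer")
  expect_warning(apply_cf(cen, cf, year = 2019), "year")
})

test_that("CF accessors, tidiers and JSON report agree", {
  pairs <- tibble::tibble(area_id = 1:35, low_mag_count = rep(10L, 35),
                          high_mag_count = rep(12L, 35))
  cf <- suppressWarnings(estimate_cf(pairs, observer_id = "o1", year = 2019L))
  td <- tidy(cf)
  expect_equal(td$estimate, 1.2)
  gl <- glance(cf)
  expect_equal(gl$n_pairs, 35)

  path <- withr::local_tempfile(fileext = ".json")
  write_cf_report(cf, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$mean_ratio, 1.2)
  expect_equal(parsed$observer_id, "o1")
})
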