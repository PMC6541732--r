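#' Chi-square goodness of fit for a fitted count distribution
#'
#' Compares observed count-class frequencies with the frequencies expected
#' under the fitted model. Count classes 0, 1, 2, ... are pooled from the
#' upper tail downward until every expected frequency reaches
#' `min_expected`; the top class absorbs the full upper tail of the model so
#' expected frequencies sum to n. The null hypothesis is that observed and
#' expected frequencies do not differ; it is rejected when the p-value falls
#' below the chosen significance level.
#'
#' Degrees of freedom are `bins - 1 - k` (k = number of estimated
#' parameters), floored at 1; when pooling leaves 2 bins or fewer the result
#' carries a low-resolution warning flag.
#'
#' @param x A census data frame or numeric count vector (the data the model
#'   was fitted to).
#' @param fitted A `count_fit` object from [fit_count_distribution()].
#' @param min_expected Minimum expected frequency per pooled bin (default 5).
#' @return An object of class `count_gof`: list with `chi2`, `df`,
#'   `p_value`, `low_resolution`, and `bins`, a tibble of
#'   `(count_class, observed, expected)` after pooling.
#' @export
chi_square_gof <- function(x, fitted, min_expected = 5) {
  stopifnot(inherits(fitted, "count_fit"))
  counts <- as_count_vector(x)
  n <- length(counts)
  pfun <- family_pfun(fitted$family)
  dfun <- family_dfun(fitted$family)
  tail_expected <- function(k) n * (1 - if (k > 0) pfun(k - 1, fitted$params) else 0)

  # top class is the open tail {>= K}, with K the largest cut whose tail
  # expectation still reaches min_expected (so classes can extend past the
  # largest observed count when the model puts enough mass there)
  K <- 1L
  while (tail_expected(K + 1L) >= min_expected && K <= max(counts) + 1000L) {
    K <- K + 1L
  }
  lo <- c(0:(K - 1L), K)
  hi <- c(0:(K - 1L), Inf)
  expected <- c(n * dfun(0:(K - 1L), fitted$params), tail_expected(K))
  observed <- c(tabulate(counts[counts < K] + 1L, nbins = K),
                sum(counts >= K))

  # pool any remaining deficient class with its upper neighbour (the top
  # class pools downward), keeping classes contiguous
  while (length(expected) > 1 && min(expected) < min_expected) {
    i <- max(which(expected < min_expected))
    j <- if (i == length(expected)) i - 1L else i + 1L
    a <- min(i, j); b <- max(i, j)
    expected[a] <- expected[a] + expected[b]
    observed[a] <- observed[a] + observed[b]
    hi[a] <- hi[b]
    expected <- expected[-b]; observed <- observed[-b]
    lo <- lo[-b]; hi <- hi[-b]
  }
  labels <- ifelse(is.infinite(hi), paste0(">=", lo),
                   ifelse(lo == hi, as.character(lo), paste0(lo, "-", hi)))

  chi2 <- sum((observed - expected)^2 / expected)
  df <- max(length(expected) - 1L - fitted$k, 1L)
  low_resolution <- length(expected) <= 2
  if (low_resolution) {
    warn("Chi-square pooling left <= 2 bins; p-value has low resolution.")
  }
  structure(list(
    chi2 = chi2,
    df = df,
    p_value = pchisq(chi2, df = df, lower.tail = FALSE),
    low_resolution = low_resolution,
    n = n,
    family = fitted$family,
    bins = tibble::tibble(count_class = labels, observed = observed,
                          expected = expected)
  ), class = "count_gof")
}

#' @export
print.count_gof <- function(x, ...) {
  cat(sprintf("<count_gof> %s: chi2 = %.4f, df = %d, p = %.4g%s\n",
              x$family, x$chi2, x$df, x$p_value,
              if (x$low_resolution) " [low resolution]" else ""))
  invisible(x)
}

#' Tidy a goodness-of-fit result
#'
#' @param x A `count_gof` object.
#' @param ... Unused.
#' @return The pooled bin table as a tibble.
#' @export
tidy.count_gof <- function(x, ...) x$bins

#' One-row summary of a goodness-of-fit result
#'
#' @inheritParams tidy.count_gof
#' @return A one-row tibble.
#' @export
glance.count_gof <- function(x, ...) {
  tibble::tibble(family = x$family, statistic = x$chi2, df = x$df,
                 p.value = x$p_value, n_bins = nrow(x$bins),
                 low_resolution = x$low_resolution)
}

#' Fit and rank candidate count models
#'
#' Fits each family, runs the chi-square goodness-of-fit test, and ranks the
#' models ascending by AIC (ties broken by BIC, then by fewer parameters).
#' A goodness-of-fit rejection flags a family but does not remove it from
#' the ranking; both criteria are reported.
#'
#' @param x A census data frame or numeric count vector.
#' @param families Character vector of families to compare; default is the
#'   three candidates: geometric, Poisson, negative binomial.
#' @param alpha Significance level for the goodness-of-fit flag.
#' @param min_expected Passed to [chi_square_gof()].
#' @return A tibble of class `model_comparison`, one row per family in rank
#'   order, with columns `family`, `aic`, `bic`, `loglik`, `k`, `chi2`, `df`,
#'   `gof_p`, `gof_reject`, `boundary` and list-columns `fit` and `gof`.
#'   Families whose fit fails are reported with `NA` statistics and ranked
#'   last.
#' @export
compare_count_models <- function(x, families = count_families(), alpha = 0.05,
                                 min_expected = 5) {
  if (length(families) == 0) {
    abort("`families` must be non-empty.", class = "cliffcensus_validation_error")
  }
  families <- match_family(families)
  counts <- as_count_vector(x)
  rows <- purrr::map(families, function(fam) {
    fit <- tryCatch(fit_count_distribution(counts, fam), error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble::tibble(
        family = fam, aic = NA_real_, bic = NA_real_, loglik = NA_real_,
        k = NA_integer_, chi2 = NA_real_, df = NA_integer_, gof_p = NA_real_,
        gof_reject = NA, boundary = NA, error = conditionMessage(fit),
        fit = list(NULL), gof = list(NULL)))
    }
    gof <- suppressWarnings(chi_square_gof(counts, fit, min_expected = min_expected))
    tibble::tibble(
      family = fam, aic = fit$aic, bic = fit$bic, loglik = fit$loglik,
      k = fit$k, chi2 = gof$chi2, df = gof$df, gof_p = gof$p_value,
      gof_reject = gof$p_value < alpha, boundary = fit$boundary,
      error = NA_character_, fit = list(fit), gof = list(gof))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, is.na(.data$aic), .data$aic, .data$bic, .data$k)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("model_comparison", class(out))
  out
}

#' Best-fitting model from a comparison
#'
#' @param comparison A `model_comparison` tibble from [compare_count_models()].
#' @return The top-ranked `count_fit` object.
#' @export
best_fit <- function(comparison) {
  stopifnot(inherits(comparison, "model_comparison"))
  fit <- comparison$fit[[1]]
  if (is.null(fit)) {
    abort("No family could be fitted.", class = "cliffcensus_fit_error")
  }
  fit
}

#' Write a model-comparison report as JSON
#'
#' One entry per family: parameters, log-likelihood, AIC, BIC, chi-square
#' statistic, degrees of freedom, p-value and the pooled bin table.
#'
#' @param comparison A `model_comparison` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(comparison, path) {
  stopifnot(inherits(comparison, "model_comparison"))
  report <- purrr::map(seq_len(nrow(comparison)), function(i) {
    fit <- comparison$fit[[i]]
    gof <- comparison$gof[[i]]
    if (is.null(fit)) {
      return(list(family = comparison$family[i], error = comparison$error[i]))
    }
    list(
      family = fit$family, rank = comparison$rank[i], params = fit$params,
      loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
      boundary = fit$boundary,
      chi2 = gof$chi2, df = gof$df, p_value = gof$p_value,
      bins = gof$bins
    )
  })
  names(report) <- comparison$family
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}
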