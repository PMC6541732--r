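# Family helpers: density, CDF, quantile, random generation, moments.
# All families live on the support {0, 1, 2, ...}. The negative binomial is
# parameterized by (size r, mean mu); convert_nb() maps to (size, prob).

family_dfun <- function(family) {
  switch(family,
    poisson   = function(x, params, log = FALSE) dpois(x, params$lambda, log = log),
    geometric = function(x, params, log = FALSE) dgeom(x, params$prob, log = log),
    nbinom    = function(x, params, log = FALSE)
      dnbinom(x, size = params$size, mu = params$mu, log = log)
  )
}

family_pfun <- function(family) {
  switch(family,
    poisson   = function(q, params) ppois(q, params$lambda),
    geometric = function(q, params) pgeom(q, params$prob),
    nbinom    = function(q, params) pnbinom(q, size = params$size, mu = params$mu)
  )
}

family_qfun <- function(family) {
  switch(family,
    poisson   = function(p, params) qpois(p, params$lambda),
    geometric = function(p, params) qgeom(p, params$prob),
    nbinom    = function(p, params) qnbinom(p, size = params$size, mu = params$mu)
  )
}

family_rfun <- function(family) {
  switch(family,
    poisson   = function(n, params) rpois(n, params$lambda),
    geometric = function(n, params) rgeom(n, params$prob),
    nbinom    = function(n, params) rnbinom(n, size = params$size, mu = params$mu)
  )
}

family_mean <- function(family, params) {
  switch(family,
    poisson   = params$lambda,
    geometric = (1 - params$prob) / params$prob,
    nbinom    = params$mu
  )
}

family_variance <- function(family, params) {
  switch(family,
    poisson   = params$lambda,
    geometric = (1 - params$prob) / params$prob^2,
    nbinom    = params$mu + params$mu^2 / params$size
  )
}

#' Convert a (size, mean) negative binomial to (size, prob)
#'
#' @param size Dispersion parameter r (> 0).
#' @param mu Mean (> 0).
#' @return A list with `size` and `prob = size / (size + mu)`.
#' @export
nb_mu_to_prob <- function(size, mu) list(size = size, prob = size / (size + mu))

#' Convert a (size, prob) negative binomial to (size, mean)
#'
#' @param size Dispersion parameter r (> 0).
#' @param prob Success probability in (0, 1].
#' @return A list with `size` and `mu = size * (1 - prob) / prob`.
#' @export
nb_prob_to_mu <- function(size, prob) list(size = size, mu = size * (1 - prob) / prob)

# Upper bound for log(size) in the NB profile optimisation. Beyond this the
# NB is numerically Poisson and the fit is flagged as a boundary case.
NB_LOG_SIZE_MAX <- 15

#' Fit a count distribution by maximum likelihood
#'
#' Fits one of the three candidate models for per-cell visual-unit counts:
#' \describe{
#'   \item{poisson}{rate `lambda`; MLE is the sample mean (closed form).}
#'   \item{geometric}{success probability `prob`, support starting at 0
#'     (number of failures, R's convention); MLE is `1 / (1 + mean)`
#'     (closed form).}
#'   \item{nbinom}{dispersion `size` (r) and mean `mu`; the mean MLE is the
#'     sample mean exactly, and `size` is found by maximising the profile
#'     log-likelihood in `log(size)` numerically.}
#' }
#' For all three families the fitted model mean equals the sample mean, which
#' the expansion estimator in the effort analysis relies on.
#'
#' When the sample variance does not exceed the mean, the NB likelihood is
#' maximised at the Poisson boundary (`size` very large); the fit is returned
#' with `boundary = TRUE` rather than failing.
#'
#' @param x A census data frame (included cells are used) or a numeric vector
#'   of non-negative integer counts, with at least 2 observations.
#' @param family `"poisson"`, `"geometric"` or `"nbinom"`
#'   (aliases `"negative_binomial"`, `"nb"`).
#' @return An object of class `count_fit`: list with `family`, `params`,
#'   `loglik`, `aic`, `bic`, `k` (number of free parameters), `n`,
#'   `boundary`, and the counts used (`counts`).
#' @examples
#' fit_count_distribution(c(3, 3, 3, 3), "poisson")$params$lambda  # 3
#' @export
fit_count_distribution <- function(x, family) {
  family <- match_family(family)
  counts <- as_count_vector(x)
  n <- length(counts)
  if (n < 2) {
    abort("Need at least 2 counts to fit a distribution.",
          class = "cliffcensus_insufficient_data_error")
  }
  m <- mean(counts)
  boundary <- FALSE
  if (family == "poisson") {
    params <- list(lambda = m)
    k <- 1L
  } else if (family == "geometric") {
    params <- list(prob = 1 / (1 + m))
    k <- 1L
  } else {
    if (m == 0) {
      abort("Cannot fit a negative binomial to all-zero counts.",
            class = "cliffcensus_validation_error")
    }
    nll <- function(log_size) {
      -sum(dnbinom(counts, size = exp(log_size), mu = m, log = TRUE))
    }
    opt <- optimize(nll, interval = c(-12, NB_LOG_SIZE_MAX), tol = 1e-10)
    log_size <- opt$minimum
    # equidispersed or underdispersed data push size to the Poisson boundary
    if (log_size > NB_LOG_SIZE_MAX - 1) {
      log_size <- NB_LOG_SIZE_MAX
      boundary <- TRUE
    }
    params <- list(size = exp(log_size), mu = m)
    k <- 2L
  }
  ll <- sum(family_dfun(family)(counts, params, log = TRUE))
  structure(list(
    family = family,
    params = params,
    loglik = ll,
    aic = 2 * k - 2 * ll,
    bic = k * log(n) - 2 * ll,
    k = k,
    n = n,
    boundary = boundary,
    counts = counts
  ), class = "count_fit")
}

#' Theoretical mean of a fitted distribution
#'
#' Poisson: `lambda`; geometric: `(1 - p) / p`; negative binomial: `mu`.
#' For fits produced by [fit_count_distribution()] this equals the sample
#' mean of the data.
#'
#' @param fitted A `count_fit` object.
#' @return A single non-negative number.
#' @export
distribution_mean <- function(fitted) {
  stopifnot(inherits(fitted, "count_fit"))
  family_mean(fitted$family, fitted$params)
}

#' Theoretical variance of a fitted distribution
#'
#' @inheritParams distribution_mean
#' @return A single non-negative number.
#' @export
distribution_variance <- function(fitted) {
  stopifnot(inherits(fitted, "count_fit"))
  family_variance(fitted$family, fitted$params)
}

#' @export
print.count_fit <- function(x, ...) {
  par_str <- paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)),
                   collapse = ", ")
  cat(sprintf("<count_fit> %s(%s), n = %d\n", x$family, par_str, x$n))
  cat(sprintf("  loglik %.3f, AIC %.3f, BIC %.3f%s\n", x$loglik, x$aic, x$bic,
              if (x$boundary) " [Poisson boundary]" else ""))
  invisible(x)
}

#' Tidy a fitted count distribution
#'
#' @param x A `count_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter.
#' @export
tidy.count_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = as.numeric(unlist(x$params)))
}

#' One-row summary of a fitted count distribution
#'
#' @inheritParams tidy.count_fit
#' @return A one-row tibble with fit statistics.
#' @export
glance.count_fit <- function(x, ...) {
  tibble::tibble(family = x$family, logLik = x$loglik, AIC = x$aic,
                 BIC = x$bic, df = x$k, nobs = x$n, boundary = x$boundary)
}
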