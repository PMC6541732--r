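#' Empirical cumulative distribution of counts
#'
#' @param x A census data frame or numeric count vector.
#' @return A tibble with `kind = "cdf"`, one row per distinct value `x`, and
#'   `y` the fraction of observations `<= x`. The last `y` is always 1.
#' @examples
#' empirical_cdf(c(0, 1, 1, 3))
#' @export
empirical_cdf <- function(x) {
  counts <- as_count_vector(x)
  if (length(counts) < 1) {
    abort("Need at least one observation.",
          class = "cliffcensus_insufficient_data_error")
  }
  v <- sort(unique(counts))
  tibble::tibble(kind = "cdf",
                 x = as.numeric(v),
                 y = vapply(v, function(q) mean(counts <= q), numeric(1)))
}

#' PP-plot series for a fitted count distribution
#'
#' For the i-th order statistic, plots the theoretical CDF evaluated there
#' (x) against the Hazen plotting position `(i - 0.5) / n` (y). Under the
#' fitted model the points fall near the identity line.
#'
#' @param x A census data frame or numeric count vector.
#' @param fitted A `count_fit` object.
#' @return A tibble with `kind = "pp"` and columns `x`, `y` in the unit
#'   square.
#' @export
pp_points <- function(x, fitted) {
  stopifnot(inherits(fitted, "count_fit"))
  counts <- sort(as_count_vector(x))
  n <- length(counts)
  if (n < 1) {
    abort("Need at least one observation.",
          class = "cliffcensus_insufficient_data_error")
  }
  pfun <- family_pfun(fitted$family)
  tibble::tibble(kind = "pp",
                 x = pfun(counts, fitted$params),
                 y = (seq_len(n) - 0.5) / n)
}

#' QQ-plot series for a fitted count distribution
#'
#' Plots theoretical quantiles (x) against empirical order statistics (y).
#' The theoretical quantile at probability p is the smallest support point
#' whose CDF reaches p (the standard discrete-quantile convention).
#'
#' @inheritParams pp_points
#' @return A tibble with `kind = "qq"` and columns `x` (theoretical
#'   quantiles, non-decreasing) and `y` (sorted counts).
#' @export
qq_points <- function(x, fitted) {
  stopifnot(inherits(fitted, "count_fit"))
  counts <- sort(as_count_vector(x))
  n <- length(counts)
  if (n < 1) {
    abort("Need at least one observation.",
          class = "cliffcensus_insufficient_data_error")
  }
  qfun <- family_qfun(fitted$family)
  p <- (seq_len(n) - 0.5) / n
  tibble::tibble(kind = "qq",
                 x = as.numeric(qfun(p, fitted$params)),
                 y = as.numeric(counts))
}

#' Density-comparison series for a fitted count distribution
#'
#' Observed relative frequency of each count class against the fitted
#' probability mass function.
#'
#' @inheritParams pp_points
#' @return A tibble with `kind = "density"`, `x` the count class, `y` the
#'   observed relative frequency and `theoretical` the model pmf.
#' @export
density_points <- function(x, fitted) {
  stopifnot(inherits(fitted, "count_fit"))
  counts <- as_count_vector(x)
  classes <- 0:max(counts)
  dfun <- family_dfun(fitted$family)
  tibble::tibble(kind = "density",
                 x = as.numeric(classes),
                 y = tabulate(counts + 1L, nbins = length(classes)) / length(counts),
                 theoretical = dfun(classes, fitted$params))
}

#' All diagnostic series for a fitted model
#'
#' @inheritParams pp_points
#' @return A tibble stacking the density, CDF (empirical and theoretical),
#'   PP and QQ series, with a `series` column distinguishing empirical from
#'   theoretical curves.
#' @export
diagnostic_series <- function(x, fitted) {
  counts <- as_count_vector(x)
  ecdf_tbl <- empirical_cdf(counts)
  pfun <- family_pfun(fitted$family)
  tcdf_tbl <- tibble::tibble(kind = "cdf", x = ecdf_tbl$x,
                             y = pfun(ecdf_tbl$x, fitted$params))
  dens <- density_points(counts, fitted)
  dplyr::bind_rows(
    dplyr::mutate(dplyr::select(dens, "kind", "x", "y"), series = "empirical"),
    tibble::tibble(kind = "density", x = dens$x, y = dens$theoretical,
                   series = "theoretical"),
    dplyr::mutate(ecdf_tbl, series = "empirical"),
    dplyr::mutate(tcdf_tbl, series = "theoretical"),
    dplyr::mutate(pp_points(counts, fitted), series = "empirical"),
    dplyr::mutate(qq_points(counts, fitted), series = "empirical")
  )
}

#' Diagnostic plot for a fitted count distribution
#'
#' Four panels: observed vs fitted probability mass, empirical vs
#' theoretical CDF, PP plot and QQ plot (the latter two with identity
#' reference lines). Theoretical curves are drawn in red, empirical in
#' black.
#'
#' @param object A `count_fit` object.
#' @param x Optional data to diagnose against; defaults to the counts the
#'   model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.count_fit <- function(object, x = NULL, ...) {
  counts <- if (is.null(x)) object$counts else as_count_vector(x)
  series <- diagnostic_series(counts, object)
  series$kind <- factor(series$kind,
                        levels = c("density", "cdf", "pp", "qq"),
                        labels = c("Probability mass", "CDF", "PP plot", "QQ plot"))
  ref <- dplyr::bind_rows(
    tibble::tibble(kind = factor("PP plot", levels = levels(series$kind)),
                   intercept = 0, slope = 1),
    tibble::tibble(kind = factor("QQ plot", levels = levels(series$kind)),
                   intercept = 0, slope = 1)
  )
  ggplot2::ggplot(series, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(data = ref,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope),
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_step(data = ~ dplyr::filter(.x, .data$kind == "CDF"),
                       ggplot2::aes(colour = .data$series)) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$kind != "CDF" &
                                                 .data$series == "empirical"),
                        colour = "black", size = 1) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$kind == "Probability mass" &
                                                .data$series == "theoretical"),
                       colour = "red") +
    ggplot2::scale_colour_manual(values = c(empirical = "black",
                                            theoretical = "red")) +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::labs(title = sprintf("Model diagnostics: %s", object$family),
                  x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Render diagnostic figures to disk
#'
#' Writes one figure per fitted model. Output format follows the file
#' extension (`.pdf`, `.png` or `.svg`).
#'
#' @param fits A list of `count_fit` objects (e.g. the `fit` column of a
#'   [compare_count_models()] result).
#' @param path Output file path; for multiple fits the family name is
#'   inserted before the extension.
#' @return Character vector of the files written, invisibly.
#' @export
render_diagnostics <- function(fits, path) {
  if (inherits(fits, "count_fit")) fits <- list(fits)
  fits <- purrr::compact(fits)
  if (length(fits) == 0) {
    abort("No fitted models to render.", class = "cliffcensus_validation_error")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(paste0("Output directory does not exist: ", dir),
          class = "cliffcensus_io_error")
  }
  ext <- tools::file_ext(path)
  stem <- sub(paste0("\\.", ext, "$"), "", path)
  files <- purrr::map_chr(fits, function(fit) {
    out <- if (length(fits) == 1) path else paste0(stem, "-", fit$family, ".", ext)
    ggplot2::ggsave(out, autoplot.count_fit(fit), width = 8, height = 6,
                    dpi = 150)
    out
  })
  invisible(files)
}
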