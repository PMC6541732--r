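#' Build a grid census from per-cell counts
#'
#' A grid census records, for each cell of the grid laid over a cliff-wall
#' photograph, the number of "visual units" counted through the telescope,
#' together with a flag saying whether the cell enters the analysis (edge
#' cells partially covering rock are usually excluded).
#'
#' @param data A data frame with columns `cell_id` and `visual_units`, and
#'   optionally `included` (logical, default `TRUE`) and `rock_fraction`
#'   (proportion of the cell covered by rock, in `[0, 1]`).
#' @param cell_size_m Side length of a (square) grid cell in metres.
#' @param wall_area_m2 Optional area of the censused wall in square metres.
#'
#' @return A tibble of class `grid_census` with columns `cell_id` (character),
#'   `visual_units` (integer), `included` (logical) and, when supplied,
#'   `rock_fraction`; the grid geometry is attached as attributes
#'   `cell_size_m` and `wall_area_m2`.
#' @examples
#' grid_census(data.frame(cell_id = c("A1", "A2", "A3"),
#'                        visual_units = c(5, 0, 12)))
#' @export
grid_census <- function(data, cell_size_m = 10, wall_area_m2 = NULL) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "cliffcensus_format_error")
  }
  missing_cols <- setdiff(c("cell_id", "visual_units"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "cliffcensus_format_error")
  }
  if (!is.numeric(cell_size_m) || cell_size_m <= 0) {
    abort("`cell_size_m` must be a positive length.",
          class = "cliffcensus_validation_error")
  }
  out <- tibble::as_tibble(data)
  out$cell_id <- as.character(out$cell_id)
  if (anyDuplicated(out$cell_id)) {
    dup <- unique(out$cell_id[duplicated(out$cell_id)])
    abort(paste0("Duplicate cell_id: ", paste(dup, collapse = ", "), "."),
          class = "cliffcensus_validation_error")
  }
  check_counts(out$visual_units, what = "visual_units", ids = out$cell_id)
  out$visual_units <- as.integer(out$visual_units)
  if (!"included" %in% names(out)) out$included <- TRUE
  out$included <- as.logical(out$included)
  if (anyNA(out$included)) {
    abort("`included` contains missing values.",
          class = "cliffcensus_validation_error")
  }
  keep <- intersect(c("cell_id", "visual_units", "included", "rock_fraction"),
                    names(out))
  out <- out[, keep]
  structure(out,
            cell_size_m = cell_size_m,
            wall_area_m2 = wall_area_m2,
            class = c("grid_census", class(tibble::tibble())))
}

validate_census <- function(census) {
  if (inherits(census, "grid_census")) {
    check_counts(census$visual_units, "visual_units", census$cell_id)
    return(census)
  }
  grid_census(census)
}

#' Read a grid census from CSV
#'
#' Expects a UTF-8 CSV with header `cell_id,visual_units[,included][,rock_fraction]`
#' and `.` as decimal separator. Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @inheritParams grid_census
#' @return A [grid_census()] tibble.
#' @export
read_census <- function(path, cell_size_m = 10, wall_area_m2 = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Census file not found: ", path),
          class = "cliffcensus_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  grid_census(raw, cell_size_m = cell_size_m, wall_area_m2 = wall_area_m2)
}

#' Write a grid census to CSV
#'
#' Round-trips with [read_census()] bit-exactly on counts and inclusion flags.
#'
#' @param census A census data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  census <- validate_census(census)
  readr::write_csv(census, path, progress = FALSE)
  invisible(path)
}

#' Exclude edge cells from a census
#'
#' Cells at the border of the photograph that cover only a sliver of rock are
#' removed from analysis to avoid the edge effect. Exclusion is by explicit
#' cell id; as a convenience, cells whose `rock_fraction` falls below a
#' threshold can be excluded as well (off by default). Counts are never
#' modified, and the operation is idempotent.
#'
#' @param census A census data frame.
#' @param cell_ids Character vector of cell ids to exclude. May be empty.
#' @param rock_fraction_min If non-`NULL` and the census has a
#'   `rock_fraction` column, additionally exclude cells with
#'   `rock_fraction < rock_fraction_min`.
#' @return The census with the listed cells flagged `included = FALSE`.
#' @export
exclude_edge_cells <- function(census, cell_ids = character(),
                               rock_fraction_min = NULL) {
  census <- validate_census(census)
  cell_ids <- as.character(cell_ids)
  unknown <- setdiff(cell_ids, census$cell_id)
  if (length(unknown) > 0) {
    abort(paste0("Unknown cell id(s): ", paste(unknown, collapse = ", "), "."),
          class = "cliffcensus_lookup_error")
  }
  census$included[census$cell_id %in% cell_ids] <- FALSE
  if (!is.null(rock_fraction_min)) {
    if (!"rock_fraction" %in% names(census)) {
      abort("`rock_fraction_min` given but census has no rock_fraction column.",
            class = "cliffcensus_format_error")
    }
    census$included[census$rock_fraction < rock_fraction_min] <- FALSE
  }
  census
}

#' Total count of a census
#'
#' Sums visual units over the included cells. When a correction factor is
#' supplied, each cell's count is multiplied by the CF mean before summing,
#' converting visual units into estimated individuals.
#'
#' @param census A census data frame.
#' @param cf Optional [correction_factor] object (or a single positive
#'   number used as the multiplier directly).
#' @return A single non-negative number.
#' @examples
#' cen <- grid_census(data.frame(cell_id = 1:3, visual_units = c(5, 0, 12)))
#' total_count(cen)          # 17
#' total_count(cen, cf = 2)  # 34
#' @export
total_count <- function(census, cf = NULL) {
  census <- validate_census(census)
  total <- sum(census$visual_units[census$included])
  if (!is.null(cf)) total <- total * cf_mean(cf)
  total
}

#' Summarize a census
#'
#' @param census A census data frame.
#' @param cf Optional correction factor applied to the corrected total.
#' @return A one-row tibble with cell counts and totals.
#' @export
census_summary <- function(census, cf = NULL) {
  census <- validate_census(census)
  inc <- census$included
  tibble::tibble(
    n_cells = nrow(census),
    n_included = sum(inc),
    n_excluded = sum(!inc),
    total_visual_units = sum(census$visual_units[inc]),
    mean_per_cell = if (any(inc)) mean(census$visual_units[inc]) else NA_real_,
    var_per_cell = if (sum(inc) > 1) var(census$visual_units[inc]) else NA_real_,
    cf_mean = if (is.null(cf)) NA_real_ else cf_mean(cf),
    corrected_total = total_count(census, cf = cf)
  )
}

#' Export a census summary as JSON
#'
#' @inheritParams census_summary
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_census_summary <- function(census, path, cf = NULL) {
  smry <- census_summary(census, cf = cf)
  jsonlite::write_json(as.list(smry), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @export
print.grid_census <- function(x, ...) {
  cat(sprintf("<grid_census> %d cells (%d included), %g m cells, total %d visual units\n",
              nrow(x), sum(x$included), attr(x, "cell_size_m") %||% 10,
              sum(x$visual_units[x$included])))
  NextMethod()
}
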