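# Small in-code fixtures shared across tests.

toy_census <- function(counts = c(5L, 0L, 12L), included = TRUE) {
  grid_census(tibble::tibble(
    cell_id = paste0("A", seq_along(counts)),
    visual_units = counts,
    included = included
  ))
}

# Independent brute-force oracle for the NB profile likelihood: a fine grid
# over log(size) with the mean fixed at the sample mean.
nb_grid_loglik <- function(counts, n_grid = 20001, lo = log(0.05), hi = log(200)) {
  m <- mean(counts)
  log_sizes <- seq(lo, hi, length.out = n_grid)
  lls <- vapply(log_sizes,
                function(ls) sum(dnbinom(counts, size = exp(ls), mu = m,
                                         log = TRUE)),
                numeric(1))
  max(lls)
}
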