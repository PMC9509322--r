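#' Bootstrap replica-sufficiency sweep of the mean rupture force
#'
#' How many SMD replicas are enough? For each candidate replica count N the
#' first N rupture forces are resampled with replacement B times; the sweep
#' records, per N, the average of the bootstrap means, the standard
#' deviation of the bootstrap means (the bootstrap standard error of the
#' ensemble mean), and the average within-resample sample SD. The SD of
#' bootstrap means shrinking with N and the mean stabilising are the
#' convergence signatures used to pick a replica count; both SD summaries
#' are reported because published convergence plots do not always say which
#' is shown.
#'
#' @param values per-replica maximum unbinding forces (pN), in replica order.
#' @param B number of bootstrap resamples per N (default 10000).
#' @param n_grid integer vector of replica counts to sweep; each must be
#'   between 2 and `length(values)`. Default `2:length(values)`.
#' @param seed integer seed; the sweep is fully deterministic given it.
#' @return Data frame with columns `n`, `mean_of_means`, `sd_of_means`,
#'   `mean_of_sds`.
#' @export
bootstrap_convergence <- function(values, B = 10000, n_grid = NULL, seed = 1L) {
  stopifnot(is.numeric(values), B >= 1)
  if (is.null(n_grid)) n_grid <- seq.int(2L, length(values))
  n_grid <- as.integer(n_grid)
  if (any(n_grid < 2L)) stop("replica counts in n_grid must be >= 2")
  if (max(n_grid) > length(values))
    stop("validation error: n_grid requests ", max(n_grid),
         " replicas but only ", length(values), " are available")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  out <- data.frame(n = n_grid, mean_of_means = NA_real_,
                    sd_of_means = NA_real_, mean_of_sds = NA_real_)
  for (r in seq_along(n_grid)) {
    N <- n_grid[r]
    draws <- matrix(sample(values[seq_len(N)], B * N, replace = TRUE), nrow = B)
    bmeans <- rowMeans(draws)
    bsds <- apply(draws, 1L, stats::sd)
    out$mean_of_means[r] <- mean(bmeans)
    out$sd_of_means[r] <- stats::sd(bmeans)
    out$mean_of_sds[r] <- mean(bsds)
  }
  out
}

# Save/restore the global RNG state so seeded package functions do not
# perturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
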