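#' Pull-force time series from one SMD replica
#'
#' Container for a single replica's pull-force trace together with the run
#' metadata needed downstream (pulling velocity, spring constant,
#' temperature). Times are in ps, forces in the native kJ/mol/nm; use
#' [kjmolnm_to_pn()] (or `force_pn()`) for the pN view.
#'
#' @param times numeric, strictly increasing sample times in ps.
#' @param forces numeric, pull force per sample in kJ/mol/nm.
#' @param velocity pulling velocity in nm/ps (> 0), or NA if unknown.
#' @param spring_k spring force constant in kJ/mol/nm^2 (> 0), or NA.
#' @param temperature simulation temperature in K (> 0), or NA.
#' @param replica_id integer replica index (>= 1), or NA.
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(times, forces, velocity = NA_real_, spring_k = NA_real_,
                        temperature = NA_real_, replica_id = NA_integer_) {
  times <- as.numeric(times)
  forces <- as.numeric(forces)
  if (length(times) != length(forces))
    stop("times and forces must have equal length")
  if (length(times) < 2L)
    stop("degenerate trace: need at least 2 samples, got ", length(times))
  if (anyNA(times) || anyNA(forces))
    stop("trace contains missing values")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  for (nm in c("velocity", "spring_k", "temperature")) {
    v <- get(nm)
    if (!is.na(v) && v <= 0) stop(nm, " must be positive")
  }
  structure(
    list(times = times, forces = forces, velocity = velocity,
         spring_k = spring_k, temperature = temperature,
         replica_id = as.integer(replica_id)),
    class = "force_trace")
}

#' @rdname force_trace
#' @param x a `force_trace`.
#' @export
force_pn <- function(x) {
  stopifnot(inherits(x, "force_trace"))
  kjmolnm_to_pn(x$forces)
}

#' COM-COM distance time series from one SMD replica
#'
#' @param times numeric, strictly increasing sample times in ps.
#' @param distances numeric, ligand-pocket centre-of-mass separation in nm
#'   (>= 0).
#' @return An object of class `distance_trace`.
#' @export
distance_trace <- function(times, distances) {
  times <- as.numeric(times)
  distances <- as.numeric(distances)
  if (length(times) != length(distances))
    stop("times and distances must have equal length")
  if (length(times) < 2L)
    stop("degenerate trace: need at least 2 samples, got ", length(times))
  if (anyNA(times) || anyNA(distances))
    stop("trace contains missing values")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(distances < 0))
    stop("distances must be non-negative")
  structure(list(times = times, distances = distances),
            class = "distance_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Pull-force trace: %d samples, t = [%g, %g] ps\n",
              length(x$times), x$times[1], x$times[length(x$times)]))
  cat(sprintf("  max force %.2f kJ/mol/nm (%.2f pN)\n",
              max(x$forces), kjmolnm_to_pn(max(x$forces))))
  if (!is.na(x$velocity))
    cat(sprintf("  v = %g nm/ps, k = %g kJ/mol/nm^2, T = %g K, replica %s\n",
                x$velocity, x$spring_k, x$temperature,
                ifelse(is.na(x$replica_id), "?", x$replica_id)))
  invisible(x)
}

#' @export
print.distance_trace <- function(x, ...) {
  cat(sprintf("COM-COM distance trace: %d samples, t = [%g, %g] ps, d = [%g, %g] nm\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              min(x$distances), max(x$distances)))
  invisible(x)
}
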