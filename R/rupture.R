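# Per-replica rupture extraction and ensemble statistics. The rupture force
# F_R^max is the global maximum of the pull-force trace (first occurrence on
# ties), interpreted as the force breaking the native ligand-receptor
# contacts at initial unbinding; the COM-COM distance at rupture is looked up
# at the nearest sample of the (more coarsely saved) distance trace.

#' Extract the rupture event from a pull-force trace
#'
#' Returns the maximum unbinding force of the replica in pN, the time of the
#' first sample attaining it, and optionally the COM-COM distance at that
#' time, taken from the distance-trace sample nearest in time (ties resolved
#' toward the earlier sample; no interpolation, matching the coarser save
#' frequency of coordinates relative to forces).
#'
#' @param force a [force_trace()].
#' @param distance optional [distance_trace()] for the same replica.
#' @return A list of class `rupture_event` with elements `f_max` (pN),
#'   `t_max` (ps) and `d_max` (nm, `NA` if no distance trace or if `t_max`
#'   lies outside its span).
#' @export
extract_rupture <- function(force, distance = NULL) {
  stopifnot(inherits(force, "force_trace"))
  i <- which.max(force$forces)       # first occurrence on ties
  f_max <- kjmolnm_to_pn(force$forces[i])
  t_max <- force$times[i]
  d_max <- NA_real_
  if (!is.null(distance)) {
    stopifnot(inherits(distance, "distance_trace"))
    tspan <- range(distance$times)
    if (t_max < tspan[1] || t_max > tspan[2]) {
      warning(sprintf(
        "t_max = %g ps outside distance-trace span [%g, %g] ps; d_max omitted",
        t_max, tspan[1], tspan[2]))
    } else {
      gaps <- abs(distance$times - t_max)
      j <- which.min(gaps)           # which.min takes the earlier on ties
      d_max <- distance$distances[j]
    }
  }
  structure(list(f_max = f_max, t_max = t_max, d_max = d_max),
            class = "rupture_event")
}

#' @export
print.rupture_event <- function(x, ...) {
  cat(sprintf("Rupture event: F_max = %.2f pN at t = %g ps", x$f_max, x$t_max))
  if (!is.na(x$d_max)) cat(sprintf(", d = %.3f nm", x$d_max))
  cat("\n")
  invisible(x)
}

#' Ensemble statistics over replicas at one pulling velocity
#'
#' Arithmetic mean and sample standard deviation (divisor N-1) of the
#' per-replica rupture force, rupture time and rupture distance, together
#' with the natural log of the loading rate for the (spring_k, velocity)
#' condition.
#'
#' @param events list of `rupture_event` objects (length >= 2).
#' @param velocity pulling velocity in nm/ps.
#' @param spring_k spring force constant in kJ/mol/nm^2.
#' @return A list of class `velocity_ensemble`: `velocity`, `spring_k`, `n`,
#'   `ln_lr`, and `mean`/`sd` named vectors over `f_max`, `t_max`, `d_max`
#'   (`d_max` entries are `NA` unless every event carries a distance), plus
#'   the per-replica `events` data frame.
#' @export
ensemble_stats <- function(events, velocity, spring_k) {
  if (length(events) < 2L)
    stop("insufficient replicas: need >= 2 rupture events, got ", length(events))
  stopifnot(all(vapply(events, inherits, logical(1), "rupture_event")))
  ev <- data.frame(f_max = vapply(events, `[[`, numeric(1), "f_max"),
                   t_max = vapply(events, `[[`, numeric(1), "t_max"),
                   d_max = vapply(events, `[[`, numeric(1), "d_max"))
  mu <- vapply(ev, mean, numeric(1))
  sg <- vapply(ev, stats::sd, numeric(1))
  if (anyNA(ev$d_max)) mu["d_max"] <- sg["d_max"] <- NA_real_
  structure(
    list(velocity = velocity, spring_k = spring_k, n = nrow(ev),
         ln_lr = loading_rate(spring_k, velocity)$ln_lr,
         mean = mu, sd = sg, events = ev),
    class = "velocity_ensemble")
}

#' @export
print.velocity_ensemble <- function(x, ...) {
  cat(sprintf("Velocity ensemble: v = %g nm/ps, k = %g kJ/mol/nm^2, N = %d, ln(LR) = %.2f\n",
              x$velocity, x$spring_k, x$n, x$ln_lr))
  cat(sprintf("  F_max = %.2f +/- %.2f pN; T_max = %.2f +/- %.2f ps",
              x$mean["f_max"], x$sd["f_max"], x$mean["t_max"], x$sd["t_max"]))
  if (!is.na(x$mean["d_max"]))
    cat(sprintf("; D_max = %.2f +/- %.2f nm", x$mean["d_max"], x$sd["d_max"]))
  cat("\n")
  invisible(x)
}

#' Average unbinding-force profile across replicas
#'
#' Bins every trace on a common time grid (default 0.1 ps bins, the force
#' save interval) and averages the per-bin means across replicas over the
#' common time span; bins beyond the shortest trace are dropped. Output
#' times are bin centres, forces in pN.
#'
#' @param traces list of [force_trace()] objects at one pulling velocity.
#' @param bin_width bin width in ps (> 0).
#' @return Data frame with columns `time` (ps, bin centres) and `force`
#'   (pN, mean across replicas).
#' @export
average_force_profile <- function(traces, bin_width = 0.1) {
  stopifnot(length(traces) >= 1L, bin_width > 0)
  stopifnot(all(vapply(traces, inherits, logical(1), "force_trace")))
  v <- unique(vapply(traces, `[[`, numeric(1), "velocity"))
  if (length(v[!is.na(v)]) > 1L)
    stop("all traces must share the same pulling velocity")
  t0 <- max(vapply(traces, function(x) min(x$times), numeric(1)))
  t1 <- min(vapply(traces, function(x) max(x$times), numeric(1)))
  if (t1 - t0 < bin_width)
    stop("validation error: no overlapping time span across traces")
  edges <- seq(t0, t1, by = bin_width)
  if (edges[length(edges)] < t1) edges <- c(edges, t1)
  nb <- length(edges) - 1L
  acc <- matrix(NA_real_, nrow = length(traces), ncol = nb)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    keep <- tr$times >= t0 & tr$times <= t1
    idx <- findInterval(tr$times[keep], edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    acc[i, ] <- as.numeric(tapply(kjmolnm_to_pn(tr$forces[keep]), factor(idx, levels = seq_len(nb)), mean))
  }
  prof <- colMeans(acc)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  ok <- !is.na(prof)
  data.frame(time = centres[ok], force = prof[ok])
}

#' Unpaired two-sample t-test from summary statistics or raw samples
#'
#' Pooled-variance two-sample t-test with df = n1 + n2 - 2 and a two-sided
#' p-value, computed either from (mean, sd, n) summaries — the form needed to
#' reanalyse published tables — or from raw samples via `x` and `y`. Welch's
#' unequal-variance form is available with `var_equal = FALSE`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (sample SD, divisor N-1).
#' @param x,y alternatively, raw numeric samples (summaries are computed).
#' @param var_equal pooled (TRUE, default) or Welch (FALSE).
#' @return List with `t`, `df`, `p_value`.
#' @examples
#' unpaired_t_test(514.99, 48.76, 41, 513.60, 60.51, 41)$p_value  # ~0.909
#' @export
unpaired_t_test <- function(mean1, sd1, n1, mean2, sd2, n2,
                            x = NULL, y = NULL, var_equal = TRUE) {
  if (!is.null(x) || !is.null(y)) {
    stopifnot(!is.null(x), !is.null(y))
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p_value = 1))
    stop("degenerate case: zero variance in both groups with unequal means")
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- se^4 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  tval <- (mean1 - mean2) / se
  list(t = tval, df = df, p_value = 2 * stats::pt(-abs(tval), df))
}
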