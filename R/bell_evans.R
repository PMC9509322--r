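# Bell-Evans analysis of constant-velocity pulling data. The most probable
# rupture force grows linearly with the natural log of the loading rate,
#
#   F = (k_B T / x_b) * ln( LR * x_b / (k_B T * k_off) ),
#
# so an ordinary least-squares line F = m * ln(LR) + c over several pulling
# velocities yields the distance to the transition state x_b = k_B T / m and,
# through the intercept, the zero-force dissociation rate k_off whose
# reciprocal is the absolute residence time.

#' Loading rate of a constant-velocity pulling experiment
#'
#' The loading rate is the product of the spring force constant and the
#' pulling velocity, converted to pN/s: `lr = spring_k * 1.66054 * velocity
#' * 1e12`.
#'
#' @param spring_k spring force constant in kJ/mol/nm^2 (> 0).
#' @param velocity pulling velocity in nm/ps (> 0).
#' @return List with `lr` (pN/s) and `ln_lr`.
#' @examples
#' loading_rate(600, 0.0001)$ln_lr  # 25.32
#' loading_rate(600, 0.0010)$ln_lr  # 27.63
#' @export
loading_rate <- function(spring_k, velocity) {
  if (any(spring_k <= 0)) stop("spring_k must be positive")
  if (any(velocity <= 0)) stop("velocity must be positive")
  lr <- spring_k * .KJ_MOL_NM_TO_PN * velocity * .PS_PER_S
  list(lr = lr, ln_lr = log(lr))
}

#' Fit the Bell-Evans force-spectroscopy model
#'
#' Ordinary (optionally weighted) least squares of mean maximum unbinding
#' force (pN) against the natural logarithm of the loading rate (pN/s),
#' followed by conversion of slope and intercept into the kinetic
#' parameters: the distance to the transition state `x_b = k_B T / m`, the
#' zero-force dissociation rate `k_off`, and the absolute residence time
#' `1 / k_off`.
#'
#' Two `k_off` estimators are provided (see [estimate_kinetics()]):
#' `"intercept_ratio"` (default) divides the magnitude of the x-intercept of
#' the fitted line by the slope, the convention used in published
#' SMD residence-time tables; `"exponential"` exponentiates the signed
#' x-intercept to recover the loading rate at which the most probable
#' rupture force vanishes, `k_off = exp(-c/m) / m`, which is the estimator
#' that exactly inverts the Bell-Evans modal-force relation.
#'
#' @param ln_lr numeric vector of ln loading rates (pN/s), or a formula
#'   `force ~ ln_lr` when `data` is supplied.
#' @param force mean maximum unbinding force per loading rate, pN.
#' @param data data frame for the formula interface.
#' @param temperature absolute temperature in K (default 303.15, a typical
#'   simulation temperature for membrane-protein systems).
#' @param estimator `"intercept_ratio"` or `"exponential"`.
#' @param weights optional per-point weights for weighted least squares
#'   (e.g. replica counts over SD^2); default unweighted.
#' @param ... unused.
#' @return An object of class `bell_evans`: coefficients, x-intercept
#'   (magnitude and signed), R^2, kinetics (`x_b` nm, `k_off` 1/s,
#'   `residence_time` s), the underlying `lm` fit, and the model frame.
#' @examples
#' tab <- data.frame(
#'   ln_lr = c(25.32, 26.71, 27.12, 27.40, 27.63),
#'   force = c(505.05, 513.60, 538.82, 526.74, 532.02))
#' fit <- bell_evans(force ~ ln_lr, data = tab)
#' coef(fit)
#' fit$kinetics
#' @export
bell_evans <- function(ln_lr, ...) UseMethod("bell_evans")

#' @rdname bell_evans
#' @export
bell_evans.formula <- function(ln_lr, data, ...) {
  mf <- stats::model.frame(ln_lr, data)
  if (ncol(mf) != 2L) stop("formula must be of the form force ~ ln_lr")
  bell_evans.default(mf[[2L]], mf[[1L]], ...)
}

#' @rdname bell_evans
#' @export
bell_evans.default <- function(ln_lr, force, temperature = 303.15,
                               estimator = c("intercept_ratio", "exponential"),
                               weights = NULL, ...) {
  estimator <- match.arg(estimator)
  stopifnot(is.numeric(ln_lr), is.numeric(force),
            length(ln_lr) == length(force))
  if (length(ln_lr) < 2L) stop("need at least 2 (ln_lr, force) points")
  if (length(unique(ln_lr)) < 2L)
    stop("singular fit: all ln_lr values identical")
  if (temperature <= 0) stop("temperature must be positive")
  dat <- data.frame(ln_lr = ln_lr, force = force)
  fit <- if (is.null(weights)) stats::lm(force ~ ln_lr, data = dat)
         else stats::lm(force ~ ln_lr, data = dat, weights = weights)
  co <- stats::coef(fit)
  m <- unname(co["ln_lr"]); cc <- unname(co["(Intercept)"])
  r2 <- stats::cor(dat$ln_lr, dat$force)^2   # squared Pearson correlation
  if (length(ln_lr) == 2L)
    warning("only 2 points: R^2 = 1 by construction")
  kin <- if (m > 0) {
    estimate_kinetics(slope = m, y_intercept = cc,
                      temperature = temperature, estimator = estimator)
  } else {
    warning("non-positive slope: kinetic parameters undefined ",
            "(rupture force must increase with loading rate)")
    list(x_b = NA_real_, k_off = NA_real_, residence_time = NA_real_,
         temperature = temperature, estimator = estimator)
  }
  structure(
    list(coefficients = c(y_intercept = cc, slope = m),
         x_intercept = abs(cc / m), x_intercept_signed = -cc / m,
         r_squared = r2, n = length(ln_lr),
         kinetics = kin, temperature = temperature, estimator = estimator,
         lm = fit, model = dat, call = match.call()),
    class = "bell_evans")
}

#' Kinetic parameters from a Bell-Evans regression
#'
#' Converts the slope and intercept of the force vs ln(loading-rate) line
#' into `x_b`, `k_off` and the residence time. Accepts either a fitted
#' [bell_evans()] object or explicit `slope` (pN per ln(pN/s)) and
#' `y_intercept` (pN).
#'
#' `"intercept_ratio"`: `k_off = b / m` with `b = |c/m|` the magnitude of the
#' x-intercept — the reported-table convention (equivalently `k_off =
#' |c|/m^2`). `"exponential"`: `k_off = exp(-c/m) / m`, i.e. the loading rate
#' `LR0` at which the modal rupture force extrapolates to zero divided by
#' the slope; this mode exactly recovers the generating parameters from
#' noiseless modal forces. The intercept-ratio form divides a ln-space
#' quantity by a pN slope and is reported as printed, without a consistent
#' unit derivation; see the package vignette.
#'
#' @param object a `bell_evans` fit (optional).
#' @param slope,y_intercept regression coefficients if no object given.
#' @param temperature absolute temperature in K.
#' @param estimator `"intercept_ratio"` or `"exponential"`.
#' @return List with `x_b` (nm), `k_off` (1/s), `residence_time` (s),
#'   `temperature`, `estimator`.
#' @examples
#' estimate_kinetics(slope = 18.79, y_intercept = 14.90)  # k_off ~ 0.042/s
#' @export
estimate_kinetics <- function(object = NULL, slope = NULL, y_intercept = NULL,
                              temperature = 303.15,
                              estimator = c("intercept_ratio", "exponential")) {
  estimator <- match.arg(estimator)
  if (!is.null(object)) {
    stopifnot(inherits(object, "bell_evans"))
    slope <- unname(object$coefficients["slope"])
    y_intercept <- unname(object$coefficients["y_intercept"])
    temperature <- object$temperature
  }
  if (is.null(slope) || is.null(y_intercept))
    stop("supply either a bell_evans object or slope and y_intercept")
  if (temperature <= 0) stop("temperature must be positive")
  if (slope <= 0)
    stop("estimator domain error: slope must be positive (got ", slope,
         "); rupture force must increase with loading rate")
  kBT <- .KB_PN_NM * temperature     # pN nm
  x_b <- kBT / slope                 # nm
  b_mag <- abs(y_intercept / slope)  # x-intercept magnitude, reported convention
  k_off <- switch(estimator,
    intercept_ratio = b_mag / slope,
    exponential = exp(-y_intercept / slope) / slope)
  list(x_b = x_b, k_off = k_off, residence_time = 1 / k_off,
       temperature = temperature, estimator = estimator)
}

#' Residence time from dissociation rate and back
#'
#' The absolute residence time is the reciprocal of the dissociation rate
#' constant; the two functions are exact inverses. Units pass through
#' (`k_off` in 1/s gives RT in s; 1/min gives min).
#'
#' @param k_off dissociation rate constant (> 0).
#' @param rt residence time (> 0).
#' @return The reciprocal.
#' @examples
#' koff_to_rt(0.0252)  # 39.68 min if k_off was per minute
#' @export
koff_to_rt <- function(k_off) {
  if (any(k_off <= 0)) stop("k_off must be positive")
  1 / k_off
}

#' @rdname koff_to_rt
#' @export
rt_to_koff <- function(rt) {
  if (any(rt <= 0)) stop("residence time must be positive")
  1 / rt
}

# ---- methods ---------------------------------------------------------------

#' @export
print.bell_evans <- function(x, digits = 4, ...) {
  cat("Bell-Evans force-spectroscopy fit\n")
  cat(sprintf("  F (pN) = %s * ln(LR) + %s,  R^2 = %s,  n = %d\n",
              format(x$coefficients["slope"], digits = digits),
              format(x$coefficients["y_intercept"], digits = digits),
              format(x$r_squared, digits = digits), x$n))
  cat(sprintf("  x-intercept |c/m| = %s (signed %s)\n",
              format(x$x_intercept, digits = digits),
              format(x$x_intercept_signed, digits = digits)))
  if (!is.na(x$kinetics$x_b))
    cat(sprintf("  x_b = %s nm,  k_off = %s 1/s,  residence time = %s s  [%s, T = %g K]\n",
                format(x$kinetics$x_b, digits = digits),
                format(x$kinetics$k_off, digits = digits),
                format(x$kinetics$residence_time, digits = digits),
                x$estimator, x$temperature))
  invisible(x)
}

#' @export
coef.bell_evans <- function(object, ...) object$coefficients

#' @export
summary.bell_evans <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$lm)),
            class = "summary.bell_evans")
}

#' @export
print.summary.bell_evans <- function(x, ...) {
  print(x$fit)
  cat("\nRegression detail:\n")
  stats::printCoefmat(x$lm_summary$coefficients)
  invisible(x)
}

#' @export
predict.bell_evans <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  stats::predict(object$lm, newdata = newdata)
}

#' @export
residuals.bell_evans <- function(object, ...) stats::residuals(object$lm)

#' @export
plot.bell_evans <- function(x, ...) {
  graphics::plot(x$model$ln_lr, x$model$force,
                 xlab = "ln(loading rate) [ln(pN/s)]",
                 ylab = expression(paste("mean ", F[R]^max, " (pN)")),
                 pch = 19, ...)
  graphics::abline(x$lm, lty = 2)
  invisible(x)
}

#' Simulate rupture forces from a fitted Bell-Evans model
#'
#' Draws single-replica rupture forces at each of the fitted loading rates
#' from the Bell rupture-force distribution parameterised by the fitted
#' `x_b` and `k_off`.
#'
#' @param object a `bell_evans` fit with defined kinetics.
#' @param nsim number of simulated replicates.
#' @param seed integer seed or NULL.
#' @param ... unused.
#' @return Data frame with `nsim` columns, one simulated rupture force (pN)
#'   per fitted point per column.
#' @export
simulate.bell_evans <- function(object, nsim = 1, seed = NULL, ...) {
  kin <- object$kinetics
  if (is.na(kin$x_b)) stop("kinetics undefined (non-positive slope)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(as.integer(seed))
  kBT <- .KB_PN_NM * object$temperature
  lr <- exp(object$model$ln_lr)
  out <- as.data.frame(
    vapply(seq_len(nsim),
           function(i) .sample_rupture(length(lr), lr, kin$x_b, kin$k_off, kBT),
           numeric(length(lr))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
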