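# Stochastic rupture simulator: the generative counterpart of the Bell-Evans
# analysis. A bond escaping over a single barrier under force F has rate
# k(F) = k_off * exp(F x_b / k_B T); under a linear ramp F = LR * t the
# survival probability is
#
#   S(F) = exp( -(k_off k_B T)/(LR x_b) * (exp(F x_b / k_B T) - 1) ),
#
# whose mode is F* = (k_B T / x_b) ln( LR x_b / (k_B T k_off) ). Rupture
# forces are drawn by inverse-CDF sampling and dressed into realistic
# pull-force traces (linear ramp + AR(1) noise, exponential post-rupture
# decay) written in the same XVG dialect the reader consumes.

#' Parameters of the Bell-model rupture generator
#'
#' @param k_off_true zero-force dissociation rate, 1/s (> 0).
#' @param x_b_true distance to the transition state, nm (> 0).
#' @param temperature K (> 0).
#' @param spring_k spring force constant, kJ/mol/nm^2 (> 0).
#' @param velocity pulling velocity, nm/ps (> 0).
#' @param noise_sd stationary SD of the AR(1) force noise, pN (>= 0).
#'   Default 20 pN, the order of published replica-to-replica rupture-force
#'   SDs.
#' @param post_rupture_decay time constant of the post-rupture force decay,
#'   ps (> 0).
#' @return List of class `bell_params` including the derived loading rate
#'   (`lr` in pN/s, `lr_ps` in pN/ps).
#' @export
bell_params <- function(k_off_true, x_b_true, temperature = 303.15,
                        spring_k = 600, velocity = 0.001,
                        noise_sd = 20, post_rupture_decay = 50) {
  vals <- c(k_off_true = k_off_true, x_b_true = x_b_true,
            temperature = temperature, spring_k = spring_k,
            velocity = velocity, post_rupture_decay = post_rupture_decay)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("validation error: all physical parameters must be positive and finite")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  lr <- loading_rate(spring_k, velocity)
  structure(list(k_off_true = k_off_true, x_b_true = x_b_true,
                 temperature = temperature, spring_k = spring_k,
                 velocity = velocity, noise_sd = noise_sd,
                 post_rupture_decay = post_rupture_decay,
                 lr = lr$lr, ln_lr = lr$ln_lr, lr_ps = lr$lr / .PS_PER_S),
            class = "bell_params")
}

#' Most probable rupture force under a linear force ramp
#'
#' The mode of the Bell rupture-force distribution,
#' `F* = (k_B T / x_b) * ln(LR x_b / (k_B T k_off))`, clamped to 0 when the
#' argument of the logarithm is <= 1 (rupture dominated by spontaneous
#' dissociation before loading).
#'
#' @param params a [bell_params()] object.
#' @return Modal rupture force in pN.
#' @export
modal_rupture_force <- function(params) {
  stopifnot(inherits(params, "bell_params"))
  kBT <- .KB_PN_NM * params$temperature
  arg <- params$lr * params$x_b_true / (kBT * params$k_off_true)
  if (arg <= 1) 0 else (kBT / params$x_b_true) * log(arg)
}

#' Analytic survival probability of the loaded bond
#'
#' `S(F)`: probability that rupture has not yet occurred when the ramp
#' reaches force `F`. `S(0) = 1` and `S` is monotonically decreasing.
#'
#' @param f force grid, pN (>= 0).
#' @param params a [bell_params()] object.
#' @return Survival probabilities.
#' @export
rupture_survival <- function(f, params) {
  stopifnot(inherits(params, "bell_params"))
  kBT <- .KB_PN_NM * params$temperature
  exp(-(params$k_off_true * kBT) / (params$lr * params$x_b_true) *
        (exp(f * params$x_b_true / kBT) - 1))
}

# inverse-CDF draw; lr in pN/s, k_off in 1/s, kBT in pN nm, x_b in nm
.sample_rupture <- function(n, lr, x_b, k_off, kBT) {
  u <- stats::runif(n)
  (kBT / x_b) * log(1 - (lr * x_b) / (k_off * kBT) * log(u))
}

#' Draw rupture forces from the Bell distribution
#'
#' Inverse-CDF sampling of the rupture-force law implied by a Bell escape
#' rate under a linear ramp: `F = (k_B T / x_b) * ln(1 - (LR x_b)/(k_off
#' k_B T) * ln U)` with `U ~ Uniform(0, 1)`. Uses (and advances) R's global
#' RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param params a [bell_params()] object.
#' @param n number of draws.
#' @return Rupture forces in pN (all >= 0).
#' @export
sample_rupture_force <- function(params, n = 1) {
  stopifnot(inherits(params, "bell_params"))
  kBT <- .KB_PN_NM * params$temperature
  .sample_rupture(n, params$lr, params$x_b_true, params$k_off_true, kBT)
}

#' Synthesize a realistic pull-force trace with a stochastic rupture
#'
#' Draws one rupture force, snaps the implied rupture time onto the 0.1 ps
#' force-output grid, and builds the trace: a linear ramp `LR * t` up to
#' rupture, exponential decay with time constant `post_rupture_decay`
#' afterwards, plus stationary AR(1) noise (correlation time 1 ps) of SD
#' `noise_sd` so the global maximum is not set by single-sample outliers. A
#' companion COM-COM distance trace at the 1 ps coordinate-output interval
#' is returned alongside. With `noise_sd = 0` the global maximum of the
#' trace is exactly the injected rupture `(t_r, F_r)`.
#'
#' @param params a [bell_params()] object.
#' @param replica_id integer tag stored on the trace.
#' @param max_samples cap on trace length (validation error beyond it).
#' @return List with `force` ([force_trace()]), `distance`
#'   ([distance_trace()]), and the injected `rupture_force` (pN) /
#'   `rupture_time` (ps).
#' @export
synthesize_force_trace <- function(params, replica_id = 1L,
                                   max_samples = 2e6) {
  stopifnot(inherits(params, "bell_params"))
  dt <- 0.1
  f_r <- sample_rupture_force(params, 1)
  t_r <- max(dt, round(f_r / params$lr_ps / dt) * dt)   # snap to force grid
  f_r <- params$lr_ps * t_r                              # keep ramp consistency
  t_end <- t_r + 5 * params$post_rupture_decay
  n <- floor(t_end / dt) + 1L
  if (n > max_samples)
    stop("validation error: trace would need ", n, " samples (cap ",
         max_samples, "); raise max_samples or the pulling velocity")
  times <- seq(0, by = dt, length.out = n)
  base <- ifelse(times <= t_r,
                 params$lr_ps * times,
                 f_r * exp(-(times - t_r) / params$post_rupture_decay))
  if (params$noise_sd > 0) {
    phi <- exp(-dt / 1)                     # 1 ps correlation time
    eps <- stats::rnorm(n, sd = params$noise_sd * sqrt(1 - phi^2))
    noise <- as.numeric(stats::filter(eps, phi, method = "recursive"))
    noise[1] <- stats::rnorm(1, sd = params$noise_sd)
    base <- base + noise
  }
  force <- force_trace(times, pn_to_kjmolnm(base),
                       velocity = params$velocity, spring_k = params$spring_k,
                       temperature = params$temperature,
                       replica_id = replica_id)
  td <- seq(0, by = 1, length.out = floor(t_end) + 1L)
  dist <- distance_trace(td, params$velocity * td)
  list(force = force, distance = dist,
       rupture_force = f_r, rupture_time = t_r)
}

#' Counter-based child seeds for reproducible ensembles
#'
#' `child = (master + 1664525 * counter) mod 2147483629` (a prime below
#' 2^31), so every derived seed is a valid R seed and each replica's random
#' stream is reproducible from the manifest alone.
#'
#' @param master master seed (integer).
#' @param counter non-negative counter.
#' @return Integer seed.
#' @export
child_seed <- function(master, counter) {
  p <- 2147483629
  as.integer((as.numeric(master) %% p + (1664525 * (as.numeric(counter) %% p)) %% p) %% p)
}

#' Write a synthetic SMD pulling ensemble as XVG files
#'
#' Generates `n_replicas` force/distance trace pairs for every parameter set
#' in `params_grid` and writes them in the GROMACS pull dialect
#' (`pullf_v<velocity>_r<replica>.xvg` / `pullx_...`), together with a YAML
#' manifest recording every generator parameter and the per-replica child
#' seed, so the whole tree can be regenerated byte-identically.
#'
#' @param params_grid list of [bell_params()] objects (one per pulling
#'   velocity).
#' @param n_replicas replicas per velocity (>= 1).
#' @param out_dir output directory.
#' @param seed master seed; child seeds are derived by a counter-based rule
#'   recorded in the manifest.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return Path to the manifest file, invisibly.
#' @export
write_ensemble <- function(params_grid, n_replicas, out_dir, seed,
                           overwrite = FALSE) {
  if (inherits(params_grid, "bell_params")) params_grid <- list(params_grid)
  stopifnot(all(vapply(params_grid, inherits, logical(1), "bell_params")),
            n_replicas >= 1)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("refusing to write into non-empty directory ", out_dir,
         " (use overwrite = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  manifest <- list(master_seed = as.integer(seed),
                   seed_rule = "child = (master + 1664525 * counter) mod 2147483629",
                   n_replicas = as.integer(n_replicas),
                   velocities = list())
  counter <- 0L
  for (p in params_grid) {
    vtag <- formatC(p$velocity, format = "g")
    reps <- list()
    for (r in seq_len(n_replicas)) {
      counter <- counter + 1L
      cs <- child_seed(seed, counter)
      set.seed(cs)
      syn <- synthesize_force_trace(p, replica_id = r)
      ftag <- sprintf("pullf_v%s_r%02d.xvg", vtag, r)
      xtag <- sprintf("pullx_v%s_r%02d.xvg", vtag, r)
      write_xvg(syn$force, file.path(out_dir, ftag),
                comments = sprintf("replica %d, child seed %d", r, cs))
      write_xvg(syn$distance, file.path(out_dir, xtag),
                comments = sprintf("replica %d, child seed %d", r, cs))
      reps[[r]] <- list(replica = r, child_seed = cs,
                        pullf = ftag, pullx = xtag,
                        rupture_force_pn = syn$rupture_force,
                        rupture_time_ps = syn$rupture_time)
    }
    manifest$velocities[[length(manifest$velocities) + 1L]] <-
      list(velocity = p$velocity, spring_k = p$spring_k,
           temperature = p$temperature, k_off_true = p$k_off_true,
           x_b_true = p$x_b_true, noise_sd = p$noise_sd,
           post_rupture_decay = p$post_rupture_decay,
           replicas = reps)
  }
  mpath <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}
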