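test_that("extract_rupture finds the first global maximum", {
  tr <- trace_pn(c(0, 1, 2), c(1, 3, 2))
  ev <- extract_rupture(tr)
  expect_equal(ev$f_max, 3)
  expect_equal(ev$t_max, 1)

  # strictly increasing ramp: rupture at the last sample
  ramp <- trace_pn(0:9, seq(1, 10))
  expect_equal(extract_rupture(ramp)$t_max, 9)

  # ties broken toward the first occurrence
  tie <- trace_pn(0:3, c(1, 5, 5, 2))
  expect_equal(extract_rupture(tie)$t_max, 1)

  # f_max dominates every sample, with equality attained
  set.seed(2)
  f <- rnorm(50)
  ev2 <- extract_rupture(trace_pn(seq_len(50), f))
  expect_true(all(ev2$f_max >= kjmolnm_to_pn(pn_to_kjmolnm(f))))
  expect_true(any(abs(ev2$f_max - f) < 1e-12))
})

test_that("rupture distance is looked up at the nearest coordinate sample", {
  tr <- trace_pn(c(0, 1.4, 2.8), c(1, 9, 2))
  d <- distance_trace(c(0, 1, 2, 3), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(extract_rupture(tr, d)$d_max, 0.2)  # t_max 1.4 -> t = 1
  # equidistant tie resolves to the earlier sample
  tr2 <- trace_pn(c(0, 1.5, 3), c(1, 9, 2))
  expect_equal(extract_rupture(tr2, d)$d_max, 0.2)
  # t_max outside the distance span: warning, d_max absent
  dshort <- distance_trace(c(0, 1), c(0.1, 0.2))
  tr3 <- trace_pn(c(0, 2, 4), c(1, 2, 9))
  expect_warning(ev <- extract_rupture(tr3, dshort), "span")
  expect_true(is.na(ev$d_max))
})

test_that("synthetic rupture injected at known (F*, t*) is recovered exactly", {
  set.seed(9)
  p <- bell_params(1, 0.2, velocity = 0.001, noise_sd = 0)
  syn <- synthesize_force_trace(p)
  ev <- extract_rupture(syn$force, syn$distance)
  expect_equal(ev$f_max, syn$rupture_force, tolerance = 1e-12)
  expect_equal(ev$t_max, syn$rupture_time, tolerance = 1e-12)
})

test_that("ensemble statistics use mean and N-1 sample SD", {
  ev <- function(f, t = 1, d = NA_real_)
    structure(list(f_max = f, t_max = t, d_max = d), class = "rupture_event")
  same <- ensemble_stats(list(ev(500), ev(500)), 0.001, 600)
  expect_equal(unname(same$mean["f_max"]), 500)
  expect_equal(unname(same$sd["f_max"]), 0)

  trio <- ensemble_stats(list(ev(490), ev(500), ev(510)), 0.001, 600)
  expect_equal(unname(trio$mean["f_max"]), 500)
  expect_equal(unname(trio$sd["f_max"]), 10)
  expect_equal(trio$n, 3)
  expect_equal(trio$ln_lr, loading_rate(600, 0.001)$ln_lr)

  # permutation invariance and mean bounded by member range
  set.seed(4)
  evs <- lapply(runif(10, 400, 600), ev)
  a <- ensemble_stats(evs, 0.001, 600)
  b <- ensemble_stats(evs[sample(10)], 0.001, 600)
  expect_equal(a$mean, b$mean)
  expect_equal(a$sd, b$sd)
  f <- vapply(evs, `[[`, numeric(1), "f_max")
  expect_true(a$mean[["f_max"]] >= min(f) && a$mean[["f_max"]] <= max(f))

  expect_error(ensemble_stats(list(ev(1)), 0.001, 600), "insufficient")
})

test_that("noise-free ensemble mean matches the analytic rupture-force mean", {
  # with no trace noise, extraction returns the sampled rupture force, so the
  # ensemble mean is an estimate of the analytic mean of the Bell density
  p <- bell_params(1, 0.2, temperature = 303.15, spring_k = 600,
                   velocity = 0.001, noise_sd = 0)
  set.seed(15)
  events <- lapply(1:41, function(r)
    extract_rupture(synthesize_force_trace(p, r)$force))
  es <- ensemble_stats(events, 0.001, 600)
  se_boot <- bootstrap_convergence(es$events$f_max, B = 2000,
                                   n_grid = 41, seed = 1)$sd_of_means
  expect_lt(abs(es$mean[["f_max"]] - analytic_mean_rupture(p)), 3 * se_boot)
})

test_that("average force profile bins and averages across replicas", {
  t <- seq(0, 10, by = 0.1)
  a <- trace_pn(t, t)
  prof <- average_force_profile(list(a, a))
  # identical traces: profile equals the trace within binning
  expect_lt(max(abs(prof$force - prof$time)), 0.06)
  b <- trace_pn(t, -t)
  prof0 <- average_force_profile(list(a, b))
  expect_true(all(abs(prof0$force) < 1e-9))
  # bins beyond the shortest trace are dropped
  short <- trace_pn(seq(0, 5, by = 0.1), seq(0, 5, by = 0.1))
  profs <- average_force_profile(list(a, short))
  expect_lte(max(profs$time), 5)
  expect_error(
    average_force_profile(list(a, trace_pn(c(20, 21), c(1, 2)))),
    "overlapping")
})

test_that("argmax of the averaged profile shifts earlier as velocity grows", {
  vels <- c(2e-4, 6e-4, 1e-3)
  set.seed(21)
  peak_t <- vapply(vels, function(v) {
    p <- bell_params(1, 0.2, velocity = v, noise_sd = 10,
                     post_rupture_decay = 20)
    traces <- lapply(1:8, function(r) synthesize_force_trace(p, r)$force)
    prof <- average_force_profile(traces)
    prof$time[which.max(prof$force)]
  }, numeric(1))
  expect_true(all(diff(peak_t) < 0))
})

test_that("pooled t-test reproduces published summary-statistics p-values", {
  # identical groups
  z <- unpaired_t_test(500, 10, 41, 500, 10, 41)
  expect_equal(z$t, 0)
  expect_equal(z$p_value, 1)
  # published rupture-force and rupture-time comparisons at v = 0.0004
  expect_equal(unpaired_t_test(514.99, 48.76, 41, 513.60, 60.51, 41)$p_value,
               0.9091, tolerance = 2e-4)
  p2 <- unpaired_t_test(1484.75, 203.58, 41, 1312.75, 174.67, 41)$p_value
  expect_equal(round(p2, 4), 1e-4)
  # antisymmetric in group order
  a <- unpaired_t_test(510, 50, 41, 490, 60, 41)
  b <- unpaired_t_test(490, 60, 41, 510, 50, 41)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$t, -b$t)
})

test_that("t-test p decreases with effect size and matches stats::t.test on raw data", {
  deltas <- seq(0, 50, by = 10)
  ps <- vapply(deltas, function(d)
    unpaired_t_test(500 + d, 50, 41, 500, 60, 41)$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))

  set.seed(8)
  x <- rnorm(20, 5, 2); y <- rnorm(25, 6, 2)
  mine <- unpaired_t_test(x = x, y = y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(unname(mine$t), unname(ref$statistic), tolerance = 1e-12)
  refw <- t.test(x, y)
  minew <- unpaired_t_test(x = x, y = y, var_equal = FALSE)
  expect_equal(minew$p_value, refw$p.value, tolerance = 1e-12)

  expect_error(unpaired_t_test(1, 0, 5, 2, 0, 5), "degenerate")
  expect_error(unpaired_t_test(1, 1, 1, 2, 1, 5), "n >= 2")
})
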