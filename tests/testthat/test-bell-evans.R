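test_that("loading rate converts spring stiffness and velocity to pN/s", {
  expect_equal(loading_rate(600, 0.0001)$ln_lr, 25.32, tolerance = 1e-3)
  expect_equal(loading_rate(600, 0.0010)$ln_lr, 27.63, tolerance = 1e-3)
  # exact log identities and bilinearity
  expect_equal(loading_rate(600, 0.0004)$ln_lr - loading_rate(600, 0.0001)$ln_lr,
               log(4), tolerance = 1e-12)
  expect_equal(loading_rate(600, 0.001)$ln_lr - loading_rate(600, 0.0001)$ln_lr,
               log(10), tolerance = 1e-12)
  expect_equal(loading_rate(1200, 0.0001)$lr, 2 * loading_rate(600, 0.0001)$lr)
  expect_error(loading_rate(-1, 0.001), "positive")
  expect_error(loading_rate(600, 0), "positive")
})

test_that("exactly collinear points are fit perfectly", {
  x <- 1:5
  fit <- bell_evans(x, 2 * x + 1)
  expect_equal(unname(coef(fit)["slope"]), 2, tolerance = 1e-12)
  expect_equal(unname(coef(fit)["y_intercept"]), 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(residuals(fit)), rep(0, 5), tolerance = 1e-10)
})

test_that("the agonist worked example reproduces the published regression", {
  tab <- table1_fixture()
  neca <- tab[tab$system == "2YDV", ]
  fit <- bell_evans(force ~ ln_lr, data = data.frame(ln_lr = neca$ln_lr,
                                                     force = neca$f_max_mean))
  expect_equal(unname(coef(fit)["slope"]), 12.63, tolerance = 0.005)
  expect_equal(unname(coef(fit)["y_intercept"]), 184.44, tolerance = 0.005)
  expect_equal(fit$x_intercept, 14.61, tolerance = 0.005)
  expect_equal(fit$kinetics$k_off, 1.16, tolerance = 0.01)
  expect_equal(fit$kinetics$residence_time, 0.86, tolerance = 0.01)
  expect_equal(fit$x_intercept_signed, -fit$x_intercept)
})

test_that("the antagonist regression reproduces the published R^2 and kinetics", {
  tab <- table1_fixture()
  zma <- tab[tab$system == "3EML", ]
  fit <- bell_evans(zma$ln_lr, zma$f_max_mean)
  expect_equal(fit$r_squared, 0.84, tolerance = 0.01)
  # slope is well conditioned; the tiny x-intercept is not (rounded inputs)
  expect_equal(unname(coef(fit)["slope"]), 18.79, tolerance = 0.005)
  expect_equal(fit$x_intercept, 0.79, tolerance = 0.15)
  expect_equal(fit$kinetics$k_off, 0.04, tolerance = 0.2)
})

test_that("OLS agrees with a normal-equations oracle on random inputs", {
  set.seed(31)
  for (i in 1:20) {
    x <- sort(runif(5, 20, 30))
    y <- 15 * x - 100 + rnorm(5, sd = 10)
    fit <- bell_evans(x, y)
    # independent oracle: closed-form normal equations
    sxx <- sum((x - mean(x))^2)
    m <- sum((x - mean(x)) * (y - mean(y))) / sxx
    cc <- mean(y) - m * mean(x)
    expect_equal(unname(coef(fit)["slope"]), m, tolerance = 1e-9)
    expect_equal(unname(coef(fit)["y_intercept"]), cc, tolerance = 1e-9)
    expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-9)
    # invariant: x_intercept * slope == |y_intercept|
    expect_equal(fit$x_intercept * abs(coef(fit)["slope"]),
                 abs(coef(fit)["y_intercept"]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("kinetic estimators convert slope and intercept as published", {
  k1 <- estimate_kinetics(slope = 18.79, y_intercept = 14.90,
                          temperature = 303.15)
  expect_equal(k1$k_off, 0.042, tolerance = 0.01)
  expect_equal(k1$x_b, 0.223, tolerance = 0.005)
  k2 <- estimate_kinetics(slope = 12.63, y_intercept = 184.44)
  expect_equal(k2$k_off, 1.16, tolerance = 0.005)
  expect_equal(k2$residence_time, 0.86, tolerance = 0.01)
  # identity case: slope 1, x-intercept magnitude 1
  k3 <- estimate_kinetics(slope = 1, y_intercept = -1)
  expect_equal(k3$k_off, 1)
  expect_equal(k3$residence_time, 1)
  expect_equal(k3$residence_time * k3$k_off, 1, tolerance = 1e-12)
  expect_error(estimate_kinetics(slope = -2, y_intercept = 1), "domain")
})

test_that("exponential-intercept mode inverts exact modal forces", {
  k_off <- 0.7; x_b <- 0.35
  ps <- lapply(c(1e-4, 3e-4, 1e-3), function(v)
    bell_params(k_off, x_b, velocity = v))
  fit <- bell_evans(vapply(ps, `[[`, numeric(1), "ln_lr"),
                    vapply(ps, modal_rupture_force, numeric(1)),
                    estimator = "exponential")
  expect_equal(fit$kinetics$x_b, x_b, tolerance = 1e-6)
  expect_equal(fit$kinetics$k_off, k_off, tolerance = 1e-6)
  # slope recovery holds in the default mode too
  fit2 <- bell_evans(fit$model$ln_lr, fit$model$force)
  expect_equal(fit2$kinetics$x_b, x_b, tolerance = 1e-6)
})

test_that("adding a constant force offset moves k_off but never x_b", {
  x <- c(25.3, 26.7, 27.1, 27.4, 27.6)
  set.seed(5)
  y <- 20 * x + 30 + rnorm(5)
  base <- bell_evans(x, y)
  shifted <- bell_evans(x, y + 50)
  expect_equal(coef(shifted)["slope"], coef(base)["slope"], tolerance = 1e-9)
  expect_equal(shifted$kinetics$x_b, base$kinetics$x_b, tolerance = 1e-9)
  expect_equal(unname(coef(shifted)["y_intercept"]),
               unname(coef(base)["y_intercept"]) + 50, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(shifted$kinetics$k_off, base$kinetics$k_off)))
  # default-mode estimator equals |c| / m^2
  m <- unname(coef(base)["slope"]); cc <- unname(coef(base)["y_intercept"])
  expect_equal(base$kinetics$k_off, abs(cc) / m^2, tolerance = 1e-12)
})

test_that("residence time and dissociation rate are exact reciprocals", {
  expect_equal(koff_to_rt(0.0252), 39.68, tolerance = 1e-3)   # per-minute units
  expect_equal(39.68 * 60, 2380.8)                            # min -> s
  expect_equal(koff_to_rt(1), 1)
  expect_equal(rt_to_koff(koff_to_rt(0.123)), 0.123, tolerance = 1e-15)
  expect_error(koff_to_rt(0), "positive")
  expect_error(rt_to_koff(-1), "positive")
})

test_that("degenerate regression inputs are rejected or flagged", {
  expect_error(bell_evans(c(1, 1, 1), c(1, 2, 3)), "singular")
  expect_error(bell_evans(1, 5), "at least 2")
  expect_warning(bell_evans(c(1, 2), c(3, 5)), "2 points")
  expect_warning(fit <- bell_evans(c(1, 2, 3), c(9, 6, 3)), "non-positive slope")
  expect_true(is.na(fit$kinetics$k_off))
})

test_that("fit methods behave like a standard model object", {
  tab <- table1_fixture()
  neca <- tab[tab$system == "2YDV", ]
  fit <- bell_evans(neca$ln_lr, neca$f_max_mean)
  expect_output(print(fit), "Bell-Evans")
  expect_output(print(summary(fit)), "Regression detail")
  expect_length(predict(fit), 5)
  expect_equal(unname(predict(fit, data.frame(ln_lr = 0))),
               unname(coef(fit)["y_intercept"]), tolerance = 1e-9)
  expect_equal(sum(residuals(fit)), 0, tolerance = 1e-9)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(5L, 3L))
  expect_true(all(sims >= 0))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
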