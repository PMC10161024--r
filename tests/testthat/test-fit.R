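times_5min <- seq(0, 300, by = 30)

test_that("an exact line is recovered with the full window and no readjustment", {
  fit <- fit_permeability(as_leakage_curve(times_5min, 5e-8 * times_5min))
  expect_equal(fit$P_hat, 5e-8)
  expect_equal(fit$window, c(0, 300))
  expect_false(fit$window_readjusted)
  expect_false(fit$floor_limited)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$barrier, -log10(5e-8))
})

test_that("fast leakage triggers a single window readjustment: 60 s above 8e-7", {
  fit <- fit_permeability(as_leakage_curve(times_5min, 9e-7 * times_5min))
  expect_equal(diff(fit$window), 60)
  expect_true(fit$window_readjusted)
  expect_equal(fit$P_hat, 9e-7)
  expect_equal(fit$n, 3L)                      # samples at 0, 30, 60 s
})

test_that("intermediate leakage refits over 120 s between 1e-7 and 8e-7", {
  fit <- fit_permeability(as_leakage_curve(times_5min, 3e-7 * times_5min))
  expect_equal(diff(fit$window), 120)
  expect_true(fit$window_readjusted)
  expect_equal(fit$P_hat, 3e-7)
})

test_that("slow leakage below 1e-7 keeps the full 0-5 min window", {
  fit <- fit_permeability(as_leakage_curve(times_5min, 9e-8 * times_5min))
  expect_equal(fit$window, c(0, 300))
  expect_false(fit$window_readjusted)
})

test_that("readjustment happens exactly once, never iteratively", {
  # concave curve: full-window slope 3e-7 selects the 120 s window; the
  # early-window slope is above 8e-7 but must NOT trigger a second pass
  y <- 1e-6 * times_5min; y[times_5min > 120] <- y[times_5min == 120]
  fit <- fit_permeability(as_leakage_curve(times_5min, y))
  first_pass <- coef(lm(y ~ times_5min))[2]
  expect_true(first_pass > 1e-7 && first_pass < 8e-7)
  expect_equal(diff(fit$window), 120)          # from the first pass only
})

test_that("a decreasing curve is clamped to the detection floor", {
  fit <- fit_permeability(as_leakage_curve(times_5min,
                                           -2e-8 * times_5min + rnorm(11, 0, 1e-9)))
  expect_true(fit$floor_limited)
  expect_equal(fit$P_hat, fit$floor)
  expect_gte(fit$P_hat, 0)
})

test_that("a slope indistinguishable from zero is floor-limited", {
  set.seed(99)
  fit <- fit_permeability(as_leakage_curve(times_5min, rnorm(11, 0, 1e-6)))
  expect_true(fit$floor_limited)
  expect_equal(fit$P_hat, qt(0.975, fit$df) * fit$se_slope)
})

test_that("hollow-channel mode fits only the 10-30 s interval", {
  t <- 0:60
  # initial filling transient before 10 s, then linear leakage at 2e-6 m/s
  y <- ifelse(t < 10, 5e-5 * t^2 / 10, 5e-4 + 2e-6 * (t - 10))
  fit <- fit_permeability(as_leakage_curve(t, y), mode = "hollow_channel")
  expect_equal(fit$window, c(10, 30))
  expect_equal(fit$P_hat, 2e-6)
  expect_equal(fit$n, 21L)
})

test_that("windows with fewer than 3 samples are an error", {
  expect_error(fit_permeability(as_leakage_curve(c(0, 300), c(0, 1e-5))),
               "fewer than 3")
  expect_error(fit_permeability(as_leakage_curve(c(0, 40, 80), 1e-6 * c(0, 40, 80)),
                                mode = "hollow_channel"),
               "fewer than 3")
  expect_error(fit_permeability(as_leakage_curve(times_5min,
                                                 c(NA, rnorm(10)))),
               "non-finite")
})

test_that("permfit behaves like a standard model object", {
  fit <- fit_permeability(as_leakage_curve(times_5min,
                                           2e-8 * times_5min + 1e-7))
  expect_named(coef(fit), c("intercept", "slope"))
  expect_equal(unname(coef(fit)["slope"]), 2e-8)
  expect_equal(predict(fit, data.frame(t = 100)), 1e-7 + 2e-8 * 100)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-20)
  expect_output(print(fit), "Permeability fit")
  expect_output(print(summary(fit)), "slope")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("the barrier-function index is -log10(P) with the tenfold identity", {
  expect_equal(barrier_function(1), 0)
  expect_equal(barrier_function(1e-7), 7)
  P <- exp(rnorm(20))
  expect_equal(barrier_function(P / 10) - barrier_function(P), rep(1, 20))
  expect_equal(barrier_function(10 * P) - barrier_function(P), rep(-1, 20))
  # strictly decreasing
  expect_true(all(diff(barrier_function(sort(P))) < 0))
  expect_error(barrier_function(0), "positive")
  expect_error(barrier_function(-1e-7), "positive")
})
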