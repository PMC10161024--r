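fit_line <- function(P) {
  t <- seq(0, 300, 30)
  fit_permeability(as_leakage_curve(t, P * t))
}

test_that("vessel-level permeability is the mean over positions", {
  same <- aggregate_vessel(lapply(rep(1e-7, 3), fit_line))
  expect_equal(same$P, 1e-7)
  expect_equal(same$barrier, 7)

  mixed <- aggregate_vessel(lapply(c(1, 2, 3) * 1e-7, fit_line))
  expect_equal(mixed$P, 2e-7)
  expect_equal(mixed$n_positions, 3L)
  expect_length(mixed$positions, 3L)
})

test_that("floor-limited positions flag the whole vessel", {
  flat <- fit_permeability(as_leakage_curve(seq(0, 300, 30),
                                            -1e-9 * seq(0, 300, 30)))
  v <- aggregate_vessel(list(fit_line(1e-7), flat))
  expect_true(v$floor_limited)
  expect_error(aggregate_vessel(list()), "no position results")
  expect_error(aggregate_vessel(list(1)), "permfit")
})

test_that("delta barrier is relative to the batch's iso-osmotic mean", {
  d <- data.frame(
    barrier = c(7.0, 7.2, 6.8, 7.66, 6.4),
    group = c("iso", "iso", "hypo", "hyper", "hypo"),
    batch = c("b1", "b1", "b1", "b1", "b1"))
  out <- delta_barrier(d)
  expect_equal(mean(out$delta_barrier[out$group == "iso"]), 0)
  expect_equal(out$delta_barrier[4], 7.66 - 7.1)
  expect_equal(out$delta_barrier[1], -0.1)
})

test_that("delta barrier is computed per batch and requires a reference in each", {
  d <- data.frame(barrier = c(7, 6, 8, 7.5), group = c("iso", "hypo", "iso", "hypo"),
                  batch = c("b1", "b1", "b2", "b2"))
  out <- delta_barrier(d)
  expect_equal(out$delta_barrier, c(0, -1, 0, -0.5))
  d$group[3] <- "hyper"
  expect_error(delta_barrier(d), "reference")
})

test_that("delta barrier is invariant to a uniform positive rescaling of P", {
  P <- c(2e-7, 1e-7, 5e-8, 3e-7)
  groups <- c("iso", "iso", "hypo", "hyper")
  base <- delta_barrier(data.frame(barrier = -log10(P), group = groups))
  for (gain in c(1e-3, 42)) {
    scaled <- delta_barrier(data.frame(barrier = -log10(gain * P),
                                       group = groups))
    expect_equal(scaled$delta_barrier, base$delta_barrier)
  }
})

test_that("paired delta barrier is before minus after", {
  expect_equal(delta_barrier_paired(c(7.5, 7.0), c(7.0, 7.2)), c(0.5, -0.2))
  expect_error(delta_barrier_paired(1:3, 1:2))
})

test_that("simulated cohorts reproduce the osmotic condition shifts", {
  co <- simulate_cohort(n_per_group = c(hypo = 200L, iso = 200L, hyper = 200L),
                        seed = 11)
  m <- tapply(log10(co$P_true), co$group, mean)
  expect_equal(unname(m["hypo"] - m["iso"]), log10(2.69), tolerance = 0.05)
  expect_equal(unname(m["iso"] - m["hyper"]), log10(7.44), tolerance = 0.05)
  expect_identical(co, simulate_cohort(
    n_per_group = c(hypo = 200L, iso = 200L, hyper = 200L), seed = 11))
})
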