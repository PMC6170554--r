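# The scenario solver: repro_fit and its methods.

test_that("the theta = 0.1 likely-midpoint scenario reproduces the headline numbers", {
  f <- repro_fit(theta = 0.1, R = 0.36, link = "offset:0.08", dist = "likely")
  expect_true(f$feasible)
  expect_equal(round_half_up(100 * f$mean_power_original), 59)
  expect_equal(round_half_up(100 * f$expected_posterior), 52)
  expect_equal(round_half_up(100 * f$mean_power_replication), 67)
  expect_equal(round_half_up(100 * f$expected_type1_share, 1), 1.2)
  expect_lt(f$residual, 1e-8)
})

test_that("a fitted solution substituted back reproduces R", {
  set.seed(41)
  for (i in 1:20) {
    th <- runif(1, 0.05, 0.8)
    fam <- sample(c("zero", "likely", "alt_small", "alt_large", "extreme"), 1)
    link <- sample(c("identical", "perfect", "offset:0.08"), 1)
    f <- repro_fit(th, R = 0.36, link = link, dist = fam)
    if (!f$feasible) next
    ep <- expected_posterior(th, 0.05, f$dist)
    R_back <- expected_reproducibility(ep, f$mean_power_replication, 0.025)
    expect_equal(R_back, 0.36, tolerance = 1e-8)
    expect_lt(f$residual, 1e-8)
    expect_gt(f$mean_power_original, 0)
    expect_lte(f$mean_power_replication, 1)
  }
})

test_that("the zero-variance fit equals the naive closed form", {
  set.seed(42)
  n_ok <- 0
  while (n_ok < 50) {
    th <- runif(1, 0.03, 0.95)
    R <- runif(1, 0.1, 0.8)
    kind <- sample(c("identical", "perfect", "offset"), 1)
    link <- if (kind == "offset") power_link("offset", runif(1, 0.02, 0.3))
            else power_link(kind)
    f <- repro_fit(th, R = R, link = link, dist = "zero")
    s <- solve_naive(R, theta = th, link = link)
    expect_identical(f$feasible, s$feasible)
    if (!f$feasible) next
    expect_equal(f$mean_power_original, s$power_original, tolerance = 1e-8)
    n_ok <- n_ok + 1
  }
})

test_that("infeasibility is reported as a value with its cause", {
  f <- repro_fit(theta = 0.02, link = "offset:0.08", dist = "likely")
  expect_false(f$feasible)
  expect_match(f$reason, "replication power")
  expect_true(is.na(f$mean_power_original))

  # a mixture whose required mean exceeds its high component mean
  f2 <- repro_fit(theta = 0.9, R = 0.95, link = "identical", dist = "alt_large")
  expect_false(f2$feasible)
  expect_match(f2$reason, "mixture")

  # R below what even minimal (alpha-floored) power produces
  f3 <- repro_fit(theta = 0.97, R = 0.04, link = "identical", dist = "likely")
  expect_false(f3$feasible)
  expect_match(f3$reason, "minimal")
})

test_that("variance raises the mean power needed to explain a replication rate", {
  for (th in c(0.1, 0.3)) {
    mus <- vapply(c("zero", "alt_small", "likely", "alt_large", "extreme"),
                  function(f) repro_fit(th, link = "offset:0.08",
                                        dist = f)$mean_power_original,
                  numeric(1))
    expect_false(is.unsorted(mus, strictly = TRUE))
  }
})

test_that("a larger replication rate needs more power", {
  mus <- vapply(c(0.27, 0.32, 0.36, 0.42, 0.46),
                function(R) repro_fit(0.1, R = R)$mean_power_original,
                numeric(1))
  expect_false(is.unsorted(mus, strictly = TRUE))
})

test_that("solved power decreases along a feasible prior sweep", {
  sw <- repro_sweep(theta = theta_grid_log(25, 0.03, 0.9))
  ok <- sw$feasible
  expect_gt(sum(ok), 20)
  expect_false(is.unsorted(rev(sw$mean_power_original[ok]), strictly = TRUE))
  # and the posterior increases with the prior
  expect_false(is.unsorted(sw$expected_posterior[ok], strictly = TRUE))
})

test_that("a one-point sweep equals a single fit", {
  sw <- repro_sweep(theta = 0.1)
  f <- repro_fit(0.1)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$mean_power_original, f$mean_power_original)
  expect_equal(sw$bias_odds, f$bias_odds)
})

test_that("a single-variant envelope collapses to that variant's sweep", {
  th <- c(0.05, 0.2)
  ev <- envelope(theta = th,
                 variants = list(list(link = "offset:0.08", dist = "likely")))
  sw <- repro_sweep(theta = th)
  expect_equal(ev$mean_power_original_min, sw$mean_power_original)
  expect_equal(ev$mean_power_original_max, sw$mean_power_original)
})

test_that("feasibility bounds match the closed-form inversions", {
  b1 <- feasibility_bound(link = "identical", dist = "zero")
  # at power = 1 the identical-link system inverts in closed form
  post_needed <- (0.36 - 0.025) / (1 - 0.025)
  th_closed <- 0.05 * post_needed / (1 - post_needed * (1 - 0.05))
  expect_lt(abs(as.numeric(b1) - th_closed), 2e-4)

  b2 <- feasibility_bound(link = "offset:0.06", dist = "likely")
  expect_lt(abs(as.numeric(b2) - 0.027), 1.5e-3)
  # perfect replication: the bound is where required original power reaches 1
  b3 <- feasibility_bound(link = "perfect", dist = "zero")
  f_above <- repro_fit(as.numeric(b3) + 2e-4, link = "perfect", dist = "zero")
  expect_true(f_above$feasible)
  expect_gt(f_above$mean_power_original, 0.97)
})

test_that("fit methods expose the solution consistently", {
  f <- repro_fit(theta = 0.1)
  cf <- coef(f)
  expect_named(cf, c("mean_power_original", "mean_power_replication",
                     "expected_posterior", "expected_positive_rate",
                     "bias_odds"))
  expect_equal(unname(cf["mean_power_original"]), f$mean_power_original)
  expect_equal(residuals(f), f$residual)
  expect_output(print(f), "expected power, original")
  expect_output(print(summary(f)), "residual")
  expect_error(repro_fit(theta = 0.1, R = 0.01), "R")
})

test_that("simulating from a fit runs the generative process at the solution", {
  f <- repro_fit(theta = 0.1)
  s1 <- simulate(f, seed = 7, n_studies = 20000)
  s2 <- simulate(f, seed = 7, n_studies = 20000)
  expect_identical(s1$n_replicated, s2$n_replicated)
  expect_equal(s1$config$theta, 0.1)
  expect_equal(mean(s1$config$dist), f$mean_power_original)
  expect_error(simulate(repro_fit(theta = 0.02), seed = 1), "infeasible")
})
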