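# Closed-form identities for a single study (zero variance in power).

test_that("positive-evidence rate follows the true/false decomposition", {
  expect_equal(prob_positive_total(0.9, 1.0, 0.05), 0.905)
  # degenerate priors collapse to power / alpha
  expect_equal(prob_positive_total(1.0, 0.7, 0.05), 0.7)
  expect_equal(prob_positive_total(0.0, 0.7, 0.05), 0.05)

  # P_true + P_false = P_total identically, and the rate is bracketed by
  # alpha and power
  set.seed(11)
  for (i in 1:200) {
    th <- runif(1); p <- runif(1); a <- runif(1)
    tot <- prob_positive_total(th, p, a)
    expect_equal(tot, th * p + a * (1 - th))
    expect_gte(tot, min(a, p) - 1e-12)
    expect_lte(tot, max(a, p) + 1e-12)
  }
  expect_error(prob_positive_total(1.2, 0.5, 0.05), "theta")
  expect_error(prob_positive_total(0.5, -0.1, 0.05), "power")
})

test_that("posterior probability matches Bayes' theorem and its limits", {
  expect_equal(posterior_prob(0.894737, 1.0, 0.05), 0.99415, tolerance = 1e-4)
  expect_equal(posterior_prob(0.5, 0.8, 0.05), 0.4 / 0.425)
  expect_equal(posterior_prob(0.3, 0.8, 0.0), 1.0)
  expect_equal(posterior_prob(1.0, 0.7, 0.05), 1.0)
  expect_equal(posterior_prob(0.0, 0.7, 0.05), 0.0)
  expect_error(posterior_prob(0.0, 0.7, 0.0), "undefined")
})

test_that("posterior is monotone in prior and power, antitone in alpha", {
  g <- seq(0.05, 0.95, length.out = 20)
  for (a in c(0.01, 0.05, 0.2)) {
    for (p in c(0.2, 0.6, 1.0)) {
      expect_false(is.unsorted(posterior_prob(g, p, a)))
    }
    for (th in c(0.1, 0.5, 0.9)) {
      expect_false(is.unsorted(posterior_prob(th, g, a)))
    }
  }
  for (th in c(0.1, 0.5, 0.9)) {
    for (p in c(0.2, 0.6, 1.0)) {
      expect_false(is.unsorted(rev(posterior_prob(th, p, g))))
    }
  }
})

test_that("positive evidence updates the prior upward iff power exceeds alpha", {
  set.seed(12)
  for (i in 1:200) {
    th <- runif(1, 0.01, 0.99)
    p <- runif(1, 0.01, 1)
    a <- runif(1, 0.01, 0.5)
    post <- posterior_prob(th, p, a)
    if (p >= a) expect_gte(post, th) else expect_lt(post, th)
  }
})

test_that("replication probability is the positive rate at the posterior", {
  expect_equal(reproducibility(0.99415, 1.0, 0.05), 0.9944, tolerance = 1e-4)
  expect_equal(reproducibility(1.0, 0.36, 0.025), 0.36)
  expect_equal(reproducibility(0.52, 0.67, 0.025), 0.3604)
  # by construction R >= alpha_r * (1 - posterior)
  set.seed(13)
  for (i in 1:100) {
    post <- runif(1); pr <- runif(1); ar <- runif(1, 0.001, 0.2)
    expect_gte(reproducibility(post, pr, ar), ar * (1 - post) - 1e-12)
  }
})

test_that("smallest prior for a target positive rate inverts the identity", {
  expect_equal(smallest_prior_for_positive_rate(0.90, 1.0, 0.05),
               0.894737, tolerance = 1e-6)
  expect_equal(smallest_prior_for_positive_rate(0.05, 1.0, 0.05), 0.0)
  expect_equal(smallest_prior_for_positive_rate(0.50, 1.0, 0.05), 0.45 / 0.95)
  # exact round trip through the forward identity
  set.seed(14)
  for (i in 1:100) {
    p <- runif(1, 0.2, 1); a <- runif(1, 0.001, 0.15)
    target <- runif(1, a, p)
    th <- smallest_prior_for_positive_rate(target, p, a)
    expect_equal(prob_positive_total(th, p, a), target)
  }
  expect_error(smallest_prior_for_positive_rate(0.5, 0.05, 0.05), "alpha")
  expect_error(smallest_prior_for_positive_rate(0.96, 0.9, 0.05), "no prior")
})

test_that("zero-variance solver recovers power under all three links", {
  # certain-true prior forces the replication rate to equal replication power
  s <- solve_naive(0.36, theta = 1, link = "identical")
  expect_true(s$feasible)
  expect_equal(s$power_original, 0.36, tolerance = 1e-9)

  # brute-force grid scan agrees for the identical link
  s2 <- solve_naive(0.36, theta = 0.1, link = "identical")
  p_scan <- grid_scan_naive(0.36, 0.1, 0.05, 0.025)
  expect_equal(s2$power_original, p_scan, tolerance = 2e-6)

  # and for an offset link
  s3 <- solve_naive(0.36, theta = 0.1, link = "offset:0.08")
  p_scan3 <- grid_scan_naive(0.36, 0.1, 0.05, 0.025, delta = 0.08)
  expect_equal(s3$power_original, p_scan3, tolerance = 2e-6)

  # perfect replication lower bound at theta = 0.05
  s4 <- solve_naive(0.36, theta = 0.05, link = "perfect")
  expect_equal(s4$power_original, 0.49727, tolerance = 1e-4)
  expect_equal(s4$power_replication, 1.0)

  # infeasibility is a value, not an exception
  s5 <- solve_naive(0.36, theta = 0.01, link = "offset:0.08")
  expect_false(s5$feasible)
  expect_match(s5$reason, "power")
})

test_that("round trip: implied R from known power is solved back exactly", {
  set.seed(15)
  n_ok <- 0
  while (n_ok < 100) {
    th <- runif(1, 0.05, 0.95)
    p <- runif(1, 0.1, 0.9)
    ao <- runif(1, 0.01, 0.1)
    ar <- runif(1, 0.01, 0.05)
    kind <- sample(c("identical", "perfect", "offset"), 1)
    link <- if (kind == "offset") power_link("offset", runif(1, 0, 1 - p))
            else power_link(kind)
    post <- posterior_prob(th, p, ao)
    pr <- switch(kind, identical = p, perfect = 1, offset = p + link$delta)
    R <- reproducibility(post, pr, ar)
    if (R <= ar || R >= 1) next
    s <- solve_naive(R, theta = th, alpha_o = ao, alpha_r = ar, link = link)
    expect_true(s$feasible)
    expect_equal(s$power_original, p, tolerance = 1e-6)
    n_ok <- n_ok + 1
  }
})

test_that("correlation-test power behaves like a power function", {
  expect_equal(correlation_power(0, 54, 0.05), 0.05)
  expect_equal(correlation_power(0, 200, 0.01), 0.01)
  # symmetric in the sign of r
  expect_equal(correlation_power(0.3, 54), correlation_power(-0.3, 54))
  # increasing in |r| and in df
  rs <- seq(0, 0.6, by = 0.1)
  expect_false(is.unsorted(correlation_power(rs, 54)))
  dfs <- c(10, 30, 54, 68, 100)
  expect_false(is.unsorted(correlation_power(0.3, dfs)))
  expect_error(correlation_power(0.3, 2), "df")
  expect_error(correlation_power(1.1, 54), "r")
})

test_that("Fisher-z power agrees with simulation of the exact test", {
  # r = 0.3 at n = 70 (the median replication study)
  mc <- mc_correlation_power(0.3, 70)
  expect_equal(correlation_power(0.3, 68), mc, tolerance = 0.02)
})
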