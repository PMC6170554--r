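# Independent oracles used across the test files.

# Round half up at d decimals (the convention used for printed percentages).
round_half_up <- function(x, d = 0) floor(x * 10^d + 0.5) / 10^d

# Brute-force zero-variance solver: scan a fine power grid and minimize
# |implied R - R|. Independent of the package's root-finder.
grid_scan_naive <- function(R, theta, alpha_o, alpha_r, delta = 0,
                            perfect = FALSE, step = 1e-6) {
  p <- seq(step, if (perfect) 1 else 1 - delta, by = step)
  post <- theta * p / (theta * p + alpha_o * (1 - theta))
  pr <- if (perfect) 1 else p + delta
  imp <- post * pr + alpha_r * (1 - post)
  p[which.min(abs(imp - R))]
}

# Monte-Carlo power of the exact two-sided test of zero correlation:
# simulate bivariate-normal samples and apply the exact t-based rejection
# rule (independent of the Fisher-z approximation under test).
mc_correlation_power <- function(r, n, alpha = 0.05, nrep = 40000,
                                 seed = 20260920) {
  set.seed(seed)
  x <- matrix(rnorm(n * nrep), n)
  y <- r * x + sqrt(1 - r^2) * matrix(rnorm(n * nrep), n)
  cx <- sweep(x, 2, colMeans(x)); cy <- sweep(y, 2, colMeans(y))
  rh <- colSums(cx * cy) / sqrt(colSums(cx^2) * colSums(cy^2))
  tcrit <- qt(1 - alpha / 2, n - 2)
  rcrit <- sqrt(tcrit^2 / (tcrit^2 + n - 2))
  mean(abs(rh) > rcrit)
}

# Numeric mean/variance/normalization of a power_dist via adaptive
# integration of its density (independent of the closed forms).
num_moment <- function(dist, fun = function(p) 1) {
  integrate(function(p) fun(p) * density(dist, p), dist$floor, 1,
            rel.tol = 1e-9, subdivisions = 500L)$value
}

# CDF of a power_dist built from pbeta (used to check the density by
# central differences).
powerdist_cdf <- function(dist, q) {
  cp <- pubbias:::.components(dist)
  u <- (q - dist$floor) / (1 - dist$floor)
  out <- numeric(length(q))
  for (i in seq_along(cp$w))
    out <- out + cp$w[i] * pbeta(u, cp$a[i], cp$b[i])
  out
}
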