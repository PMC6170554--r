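# Variance-aware expectations over a distribution of per-study power.
#
# Quadrature: expectations against a Beta component are computed by the
# probability-integral substitution u = F(x), so that
#   E[h(X)] = int_0^1 h(F^{-1}(u)) du
# evaluated with Gauss-Legendre nodes. The substitution absorbs the endpoint
# singularities of Beta densities with shapes below 1, leaving a smooth
# integrand. A node-doubling check (512 vs 1024 nodes) guards accuracy; if it
# moves the result by more than 1e-8 the adaptive integrator takes over.

.gl_cache <- new.env(parent = emptyenv())
.gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]]))
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  .gl_cache[[key]]
}

# E[h(power)] under a resolved power_dist; h must be vectorized and bounded.
expect_power <- function(dist, h) {
  stopifnot(inherits(dist, "power_dist"))
  if (is.na(dist$mu)) stop("distribution mean is unresolved", call. = FALSE)
  if (dist$family == "point") return(h(dist$mu))
  cp <- .components(dist)
  sc <- 1 - dist$floor
  one <- function(a, b, n) {
    gl <- .gl_nodes(n)
    sum(gl$w * h(dist$floor + sc * qbeta(gl$x, a, b)))
  }
  total <- 0
  for (i in seq_along(cp$w)) {
    e512 <- one(cp$a[i], cp$b[i], 512L)
    e1024 <- one(cp$a[i], cp$b[i], 1024L)
    e <- e1024
    if (abs(e1024 - e512) > 1e-8) {
      # adaptive refinement in the quantile domain, where the integrand is
      # bounded even for shapes far below 1
      e <- integrate(function(u) h(dist$floor + sc * qbeta(u, cp$a[i], cp$b[i])),
                     0, 1, rel.tol = 1e-10, abs.tol = 1e-12,
                     subdivisions = 400L)$value
    }
    total <- total + cp$w[i] * e
  }
  total
}

#' Expected posterior probability under a power distribution
#'
#' Integrates the single-study posterior over the distribution of per-study
#' power:
#' \deqn{E[\hat\theta] = \int \frac{\theta p}{\theta p + \alpha(1-\theta)}
#'   \, f(p)\, dp,}
#' the per-study (unweighted) expectation of the posterior. For a point mass
#' it equals [posterior_prob()] exactly. Because the integrand is concave in
#' power, spreading power across studies at a fixed mean can only lower the
#' expected posterior (Jensen).
#'
#' @param theta Prior probability, in \[0,1\].
#' @param alpha_o Type-1 error rate of the original studies.
#' @param dist A resolved [power_dist()].
#' @return \eqn{E[\hat\theta]} in \[0,1\].
#' @examples
#' d <- power_dist("beta", mu = 0.59, s = 0.5)
#' expected_posterior(0.1, 0.05, d)
#' @export
expected_posterior <- function(theta, alpha_o, dist) {
  .check_prob(theta, "theta")
  .check_prob(alpha_o, "alpha_o", strict = TRUE)
  if (theta == 0) return(0)
  if (theta == 1) return(1)
  c0 <- alpha_o * (1 - theta)
  expect_power(dist, function(p) theta * p / (theta * p + c0))
}

#' Expected replication rate from the expected posterior
#'
#' The affine identity
#' \eqn{E[R] = E[\hat\theta]\,(1-\beta_r) + \alpha_r (1 - E[\hat\theta])}:
#' a scalar replication power multiplies the expected posterior. The
#' across-study covariance between posterior and replication power is
#' deliberately not integrated jointly here; see the methods vignette.
#'
#' @param expected_post Expected posterior probability \eqn{E[\hat\theta]}.
#' @param mean_power_r Mean power of the replication studies.
#' @param alpha_r Type-1 error rate of the replication studies.
#' @return The expected replication rate.
#' @examples
#' expected_reproducibility(0.52, 0.67, 0.025)  # ~0.36
#' @export
expected_reproducibility <- function(expected_post, mean_power_r, alpha_r) {
  .check_prob(expected_post, "expected_post")
  .check_prob(mean_power_r, "mean_power_r")
  .check_prob(alpha_r, "alpha_r")
  expected_post * mean_power_r + alpha_r * (1 - expected_post)
}

#' Expected share of replications that are type-1 errors
#'
#' The false-positive term of the expected replication rate:
#' \eqn{\alpha_r (1 - E[\hat\theta])}.
#'
#' @inheritParams expected_reproducibility
#' @return The expected type-1 share among replications.
#' @examples
#' expected_type1_share(0.52, 0.025)  # 0.012
#' @export
expected_type1_share <- function(expected_post, alpha_r) {
  .check_prob(expected_post, "expected_post")
  .check_prob(alpha_r, "alpha_r")
  alpha_r * (1 - expected_post)
}

#' Pooled posterior: the share of positive findings that are true
#'
#' Distinct from [expected_posterior()]: conditioning on having observed a
#' positive finding weights each study by its probability of producing one,
#' so the fraction of positive findings that are true is
#' \deqn{\frac{\theta\,\mu}{\theta\,\mu + \alpha(1-\theta)}}
#' with \eqn{\mu} the mean power — the posterior evaluated at the mean, not
#' the mean of the posterior. This is the quantity a generative simulation of
#' the literature actually produces, and [simulate_studies()] validates
#' against it.
#'
#' @inheritParams expected_posterior
#' @return The pooled posterior probability.
#' @export
pooled_posterior <- function(theta, alpha_o, dist) {
  .check_prob(theta, "theta")
  .check_prob(alpha_o, "alpha_o", strict = TRUE)
  if (is.na(dist$mu)) stop("distribution mean is unresolved", call. = FALSE)
  posterior_prob(theta, dist$mu, alpha_o)
}
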