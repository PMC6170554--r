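# Closed-form single-study identities (zero variance in power).

.check_prob <- function(x, name, strict = FALSE) {
  if (!is.numeric(x) || anyNA(x))
    stop(sprintf("'%s' must be numeric and non-missing", name), call. = FALSE)
  lo <- if (strict) all(x > 0) else all(x >= 0)
  hi <- if (strict) all(x < 1) else all(x <= 1)
  if (!lo || !hi)
    stop(sprintf("'%s' must lie in %s", name,
                 if (strict) "(0,1)" else "[0,1]"), call. = FALSE)
  invisible(x)
}

#' Total probability of observing positive evidence
#'
#' The probability that a single study reports a positive (significant)
#' finding: true positives \eqn{\theta(1-\beta)} plus false positives
#' \eqn{\alpha(1-\theta)}.
#'
#' @param theta Prior probability that the tested hypothesis is true, in
#'   \[0,1\].
#' @param power Statistical power \eqn{1-\beta} of the study, in \[0,1\].
#' @param alpha Type-1 error rate of the test, in \[0,1\].
#' @return The positive-evidence rate \eqn{\theta\,(1-\beta) + \alpha(1-\theta)}.
#' @examples
#' prob_positive_total(0.9, 1, 0.05)   # 0.905: near-perfect confirmatory research
#' @seealso [posterior_prob()], [expected_positive_rate()]
#' @export
prob_positive_total <- function(theta, power, alpha) {
  .check_prob(theta, "theta"); .check_prob(power, "power"); .check_prob(alpha, "alpha")
  theta * power + alpha * (1 - theta)
}

#' Posterior probability of a positive finding
#'
#' Bayes' theorem for a binary hypothesis under NHST: the probability that a
#' hypothesis is true given that a study reported a positive finding,
#' \deqn{\hat\theta = \frac{\theta(1-\beta)}{\theta(1-\beta)+\alpha(1-\theta)}.}
#'
#' @inheritParams prob_positive_total
#' @return The posterior probability \eqn{\hat\theta} in \[0,1\].
#' @examples
#' posterior_prob(0.894737, 1, 0.05)  # ~0.994
#' @export
posterior_prob <- function(theta, power, alpha) {
  .check_prob(theta, "theta"); .check_prob(power, "power"); .check_prob(alpha, "alpha")
  denom <- theta * power + alpha * (1 - theta)
  if (any(denom <= 0))
    stop("posterior undefined: zero probability of observing positive evidence",
         call. = FALSE)
  theta * power / denom
}

#' Probability that a positive finding replicates
#'
#' A published positive finding replicates if an independent study of the same
#' hypothesis reports a positive result. This is the positive-evidence rate
#' evaluated at the finding's posterior probability:
#' \deqn{R = \hat\theta\,(1-\beta_r) + \alpha_r (1-\hat\theta).}
#'
#' @param posterior Posterior probability \eqn{\hat\theta} of the finding.
#' @param power_r Statistical power of the replication study.
#' @param alpha_r Type-1 error rate of the replication test.
#' @return The replication probability \eqn{R}.
#' @examples
#' p <- posterior_prob(0.894737, 1, 0.05)
#' reproducibility(p, 1, 0.05)  # ~0.994
#' @export
reproducibility <- function(posterior, power_r, alpha_r) {
  .check_prob(posterior, "posterior"); .check_prob(power_r, "power_r")
  .check_prob(alpha_r, "alpha_r")
  posterior * power_r + alpha_r * (1 - posterior)
}

#' Smallest prior compatible with a target positive-evidence rate
#'
#' Inverts the positive-evidence identity in \eqn{\theta}: the prior needed to
#' observe positive evidence at `target_rate` given `power` and `alpha` is
#' \eqn{\theta = (rate - \alpha)/(power - \alpha)}. With perfect power this is
#' the smallest prior able to produce the target rate.
#'
#' @param target_rate Desired positive-evidence rate, must lie in
#'   \[`alpha`, `power`\].
#' @inheritParams prob_positive_total
#' @return The prior \eqn{\theta} in \[0,1\].
#' @examples
#' smallest_prior_for_positive_rate(0.90, 1, 0.05)  # 0.8947: the 89.5% prior
#' @export
smallest_prior_for_positive_rate <- function(target_rate, power, alpha) {
  .check_prob(target_rate, "target_rate"); .check_prob(power, "power")
  .check_prob(alpha, "alpha")
  if (power == alpha)
    stop("power equals alpha: every prior yields the same positive rate",
         call. = FALSE)
  if (target_rate < min(alpha, power) || target_rate > max(alpha, power))
    stop("no prior in [0,1] attains 'target_rate': it must lie between alpha and power",
         call. = FALSE)
  (target_rate - alpha) / (power - alpha)
}

#' Solve the zero-variance system for original-study power
#'
#' Treats all studies as sharing one power value and solves the coupled
#' identities (posterior as a function of power, replication rate as a
#' function of the posterior) for the power of the original studies that
#' makes the implied replication rate equal the observed `R`, given the prior
#' `theta` and a [power_link()] between original and replication power.
#'
#' The implied replication rate is strictly increasing in power under all
#' three linkages, so a sign check over the bracket decides feasibility and
#' Brent's method finds the root. Infeasibility (no root in (0,1\], or an
#' offset link implying replication power above 1) is reported as a value,
#' not an error.
#'
#' @param R Observed replication rate, in (0,1).
#' @param theta Assumed prior probability, in (0,1\].
#' @param alpha_o Type-1 error rate of the original studies.
#' @param alpha_r Type-1 error rate of the replication studies.
#' @param link A [power_link()] (or a string such as `"identical"`,
#'   `"perfect"`, `"offset:0.08"`).
#' @return An object of class `"naive_result"`: a list with elements
#'   `power_original`, `power_replication`, `posterior`, `reproducibility`,
#'   `feasible` and `reason` (`NA` unless infeasible).
#' @examples
#' solve_naive(0.36, theta = 0.05, link = "perfect")   # lower-bound power ~0.50
#' @export
solve_naive <- function(R, theta, alpha_o = 0.05, alpha_r = 0.025,
                        link = power_link("identical")) {
  .check_prob(R, "R", strict = TRUE)
  .check_prob(theta, "theta")
  if (theta <= 0) stop("'theta' must be positive", call. = FALSE)
  .check_prob(alpha_o, "alpha_o", strict = TRUE)
  .check_prob(alpha_r, "alpha_r", strict = TRUE)
  link <- as_power_link(link)

  g <- function(p) {
    post <- posterior_prob(theta, p, alpha_o)
    reproducibility(post, replication_power(link, p), alpha_r) - R
  }
  lo <- 1e-9
  hi <- if (link$kind == "offset") 1 - link$delta else 1
  out <- list(power_original = NA_real_, power_replication = NA_real_,
              posterior = NA_real_, reproducibility = NA_real_,
              feasible = FALSE, reason = NA_character_)
  class(out) <- "naive_result"
  if (hi <= lo) {
    out$reason <- "replication power would exceed 1 for any original power"
    return(out)
  }
  if (g(lo) > 0 || g(hi) < 0) {
    out$reason <- "no power in (0,1] reproduces R under this link"
    return(out)
  }
  p <- uniroot(g, c(lo, hi), tol = 1e-12)$root
  out$power_original <- p
  out$power_replication <- replication_power(link, p)
  out$posterior <- posterior_prob(theta, p, alpha_o)
  out$reproducibility <- reproducibility(out$posterior, out$power_replication, alpha_r)
  out$feasible <- TRUE
  out
}

#' @export
print.naive_result <- function(x, ...) {
  if (!x$feasible) {
    cat("Zero-variance solution: infeasible (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "Zero-variance solution:\n  power (original)    %6.3f\n  power (replication) %6.3f\n  posterior           %6.3f\n  implied R           %6.3f\n",
      x$power_original, x$power_replication, x$posterior, x$reproducibility))
  }
  invisible(x)
}

#' Power of a two-sided test of zero correlation
#'
#' Fisher z-transform approximation: \eqn{\hat z = \mathrm{atanh}(\hat r)} is
#' treated as normal with mean \eqn{\mathrm{atanh}(r)} and variance
#' \eqn{1/(n-3)}, where the sample size is `df + 2`. This is the standard
#' approximation used by power calculators; it agrees with the exact
#' noncentral distribution to about one percentage point at these sample
#' sizes.
#'
#' @param r True correlation effect size, \eqn{|r| < 1}.
#' @param df Degrees of freedom of the test (sample size minus 2), at least 3.
#' @param alpha Two-sided test level.
#' @return The power of the test; equals `alpha` at `r = 0`.
#' @examples
#' # a median replication (df = 68) vs a median original study (df = 54)
#' correlation_power(0.3, 68) - correlation_power(0.3, 54)  # ~0.10
#' @export
correlation_power <- function(r, df, alpha = 0.05) {
  if (!is.numeric(r) || anyNA(r) || any(abs(r) >= 1))
    stop("'r' must satisfy |r| < 1", call. = FALSE)
  if (!is.numeric(df) || anyNA(df) || any(df < 3))
    stop("'df' must be at least 3", call. = FALSE)
  .check_prob(alpha, "alpha", strict = TRUE)
  n <- df + 2
  z <- atanh(abs(r)) * sqrt(n - 3)
  zc <- qnorm(1 - alpha / 2)
  pnorm(z - zc) + pnorm(-z - zc)
}
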