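# The central estimator: solve one scenario for the expected power of the
# original studies, given an observed replication rate and an assumed prior.

#' Fit the replication-rate model for one assumed prior
#'
#' Finds the mean power of the original studies such that the expected
#' replication rate implied by the model equals the observed rate `R`. The
#' model couples two identities: the expected posterior probability of a
#' positive finding, integrated over a distribution of per-study power with
#' free mean \eqn{\mu} ([expected_posterior()]), and the affine replication
#' identity ([expected_reproducibility()]) with replication power tied to
#' \eqn{\mu} through a [power_link()]. The implied replication rate is
#' strictly increasing in \eqn{\mu}, so the solution is a bracketed root.
#'
#' From the solved mean power the fit also reports the expected posterior of
#' the original findings, the expected rate of positive evidence
#' \eqn{\theta\mu + \alpha_o(1-\theta)} (linear in mean power, hence valid
#' under any power variance), and the publication-bias odds of that rate
#' against a literature with `literature_share` positive findings.
#'
#' Infeasibility — no mean power in the admissible range reproduces `R`, an
#' offset link implying replication power above 1, or a mixture mean outside
#' its component means — is reported as a value (`feasible = FALSE` plus a
#' `reason`), never as an error, so grids of fits never abort.
#'
#' @param theta Assumed prior probability of the tested hypotheses, in (0,1).
#' @param R Observed replication rate, in (`alpha_r`, 1).
#' @param alpha_o Type-1 error rate of the original studies.
#' @param alpha_r Type-1 error rate of the replication studies (0.025 by
#'   default: a two-tailed test of a directional finding).
#' @param link Power linkage between original and replication studies; a
#'   [power_link()] or string spec. Default: replication power 8 points above
#'   original power, the midpoint of the likely 6--10 point range.
#' @param dist Distribution family for per-study power with free mean; a
#'   [power_dist()] (mean `NA`), preset name or spec string. Default
#'   `"likely"` (Beta, s = 1/2).
#' @param literature_share Share of positive findings in the published
#'   literature against which bias odds are computed.
#' @return An object of class `"repro_fit"` with components
#'   `mean_power_original`, `mean_power_replication`, `expected_posterior`,
#'   `expected_positive_rate`, `expected_type1_share`, `bias_odds`,
#'   `feasible`, `reason`, `residual`, and the scenario inputs.
#' @examples
#' fit <- repro_fit(theta = 0.1)
#' fit
#' coef(fit)
#' @seealso [repro_sweep()] for grids of priors, [solve_naive()] for the
#'   zero-variance closed form, [simulate_studies()] for generative checks.
#' @export
repro_fit <- function(theta, R = 0.36, alpha_o = 0.05, alpha_r = 0.025,
                      link = power_link("offset", 0.08), dist = "likely",
                      literature_share = 0.9) {
  .check_prob(theta, "theta", strict = TRUE)
  .check_prob(alpha_o, "alpha_o", strict = TRUE)
  .check_prob(alpha_r, "alpha_r", strict = TRUE)
  .check_prob(literature_share, "literature_share", strict = TRUE)
  if (!is.numeric(R) || R <= alpha_r || R >= 1)
    stop("'R' must lie in (alpha_r, 1)", call. = FALSE)
  link <- as_power_link(link)
  dist <- parse_power_dist(dist)

  out <- structure(list(
    theta = theta, R = R, alpha_o = alpha_o, alpha_r = alpha_r,
    link = link, dist = dist, literature_share = literature_share,
    mean_power_original = NA_real_, mean_power_replication = NA_real_,
    expected_posterior = NA_real_, expected_positive_rate = NA_real_,
    expected_type1_share = NA_real_, bias_odds = NA_real_,
    feasible = FALSE, reason = NA_character_, residual = NA_real_),
    class = "repro_fit")

  # Admissible bracket for the mean power.
  eps <- 1e-9
  lo <- dist$floor + 1e-6
  hi <- if (link$kind == "offset") 1 - link$delta else 1 - eps
  clipped_hi <- FALSE
  if (dist$family == "bimodal") {
    lo <- max(lo, dist$m_lo + eps)
    if (dist$m_hi - eps < hi) { hi <- dist$m_hi - eps; clipped_hi <- TRUE }
  }
  if (lo >= hi) {
    out$reason <- "empty admissible range for mean power"
    return(out)
  }

  g <- function(mu) {
    ep <- expected_posterior(theta, alpha_o, set_mean(dist, mu))
    expected_reproducibility(ep, replication_power(link, mu), alpha_r) - R
  }

  # The implied replication rate must be increasing in mean power; verify on
  # a coarse grid before trusting the bracketed root.
  probe <- vapply(lo + (hi - lo) * c(0, 0.5, 1), g, numeric(1))
  if (is.unsorted(probe, strictly = FALSE))
    stop("implied replication rate is not monotone in mean power; cannot solve",
         call. = FALSE)

  if (probe[1] > 0) {
    out$reason <- "no root: even the minimal mean power over-reproduces R"
    return(out)
  }
  if (probe[3] < 0) {
    out$reason <- if (link$kind == "offset" && !clipped_hi)
      "replication power would exceed 1"
    else if (clipped_hi)
      "mixture mean out of range"
    else
      "no root: R is unattainable even at perfect power"
    return(out)
  }

  mu <- uniroot(g, c(lo, hi), tol = 1e-12)$root
  d <- set_mean(dist, mu)
  ep <- expected_posterior(theta, alpha_o, d)
  out$dist <- d
  out$mean_power_original <- mu
  out$mean_power_replication <- replication_power(link, mu)
  out$expected_posterior <- ep
  out$expected_type1_share <- expected_type1_share(ep, alpha_r)
  out$expected_positive_rate <- prob_positive_total(theta, mu, alpha_o)
  out$bias_odds <- bias_odds(out$expected_positive_rate, literature_share)
  out$residual <- abs(expected_reproducibility(ep, out$mean_power_replication,
                                               alpha_r) - R)
  out$feasible <- TRUE
  out
}

#' @export
print.repro_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Replication-rate fit (R = %g, theta = %g)\n", x$R, x$theta))
  cat(sprintf("  link: %s   power distribution: %s\n",
              format(x$link), format(x$dist)))
  if (!x$feasible) {
    cat("  infeasible:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  expected power, original studies     %6.1f%%\n",
              100 * x$mean_power_original))
  cat(sprintf("  expected power, replication studies  %6.1f%%\n",
              100 * x$mean_power_replication))
  cat(sprintf("  expected posterior of findings       %6.1f%%\n",
              100 * x$expected_posterior))
  cat(sprintf("  expected positive-evidence rate      %6.1f%%\n",
              100 * x$expected_positive_rate))
  cat(sprintf("  bias odds (vs %2.0f%% positive literature) %6.1f\n",
              100 * x$literature_share, x$bias_odds))
  invisible(x)
}

#' @export
summary.repro_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.repro_fit")
}

#' @export
print.summary.repro_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (f$feasible) {
    cat(sprintf("  expected type-1 share among replications: %.2f%%\n",
                100 * f$expected_type1_share))
    cat(sprintf("  solver residual |E[R] - R|: %.2e\n", f$residual))
    cat(sprintf("  power variance at solution: %.4f\n", dist_variance(f$dist)))
  }
  invisible(x)
}

#' @export
coef.repro_fit <- function(object, ...) {
  c(mean_power_original = object$mean_power_original,
    mean_power_replication = object$mean_power_replication,
    expected_posterior = object$expected_posterior,
    expected_positive_rate = object$expected_positive_rate,
    bias_odds = object$bias_odds)
}

#' @export
residuals.repro_fit <- function(object, ...) object$residual

#' Simulate the publication process at a fitted scenario
#'
#' Draws `nsim` independent simulated literatures from the generative process
#' at the solved scenario (prior, solved power distribution, link, error
#' rates), each of `n_studies` studies. See [simulate_studies()].
#'
#' @param object A feasible [repro_fit()].
#' @param nsim Number of simulated literatures.
#' @param seed Optional seed passed to the first simulation; subsequent
#'   simulations continue the RNG stream.
#' @param n_studies Studies per simulated literature.
#' @param ... Passed on to [simulate_studies()].
#' @return A single `"sim_result"` if `nsim = 1`, else a list of them.
#' @export
simulate.repro_fit <- function(object, nsim = 1, seed = NULL,
                               n_studies = 100000, ...) {
  if (!object$feasible)
    stop("cannot simulate an infeasible fit", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sims <- lapply(seq_len(nsim), function(i)
    simulate_studies(n_studies = n_studies, theta = object$theta,
                     dist = object$dist, alpha_o = object$alpha_o,
                     alpha_r = object$alpha_r, link = object$link, ...))
  if (nsim == 1) sims[[1]] else sims
}
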