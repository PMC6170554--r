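# Generative simulator of the study -> publication -> replication process.
#
# RNG usage order is fixed and documented so that seeded runs are portable:
#   1. truth        (one uniform per study)
#   2. power        (mixture component uniforms, then one rbeta call)
#   3. outcome      (one uniform per study)
#   4. publication  (one uniform per study)
#   5. replication  (one uniform per study)

#' Simulate a literature of studies, publications and replications
#'
#' Draws a literature from the generative process underlying the closed
#' forms: each study tests a true hypothesis with probability `theta`; its
#' power is drawn from `dist`; it reports a positive finding with probability
#' equal to its power (true hypotheses) or `alpha_o` (false ones). Positive
#' findings are always published; negative ones are published with
#' probability `1 / suppression_odds`. Every published positive finding is
#' replicated once: a true finding replicates with the replication power
#' implied by `link`, a false one with probability `alpha_r`.
#'
#' With `replication = "mean"` (default) the replication success probability
#' for true findings is the scalar implied by the link at the *mean* power of
#' `dist`, mirroring the affine replication identity the solver uses. With
#' `replication = "per_study"` each study's own drawn power (plus any offset)
#' is used instead; an offset that pushes any study's replication power above
#' 1 is an error, mirroring the solver's infeasibility rule.
#'
#' Alongside the empirical rates the result carries two sets of predictions,
#' both computed by quadrature: `predicted`, the generative expectations the
#' empirical rates converge to (positive rate \eqn{\theta\mu+\alpha_o(1-\theta)};
#' pooled posterior share; replication rate given the chosen replication
#' mode), and `closed_form`, the per-study expectations
#' ([expected_posterior()] / [expected_reproducibility()]) that the solver
#' matches to an observed R. The two differ because conditioning on a
#' positive finding weights studies by their positive-rate; reporting both
#' makes that gap visible rather than hiding it (see the methods vignette).
#'
#' @param n_studies Number of studies to simulate, at least 1.
#' @param theta Prior probability of a true hypothesis.
#' @param dist A resolved [power_dist()] (or spec string with `mu` set).
#' @param alpha_o,alpha_r Type-1 error rates of originals and replications.
#' @param link A [power_link()] or string spec.
#' @param suppression_odds Odds of observing a negative result per negative
#'   result published; 1 means unbiased publication.
#' @param seed Optional integer seed (fixed seed implies identical output).
#' @param replication `"mean"` or `"per_study"` (see Details).
#' @return An object of class `"sim_result"`: counts (`n_true`, `n_positive`,
#'   `n_published_positive`, `n_published_negative`, `n_replicated`),
#'   empirical rates (`empirical_positive_rate`, `empirical_reproducibility`,
#'   `empirical_posterior_share`), and the `predicted` and `closed_form`
#'   expectation lists.
#' @examples
#' d <- power_dist("beta", mu = 0.6, s = 0.5)
#' simulate_studies(10000, theta = 0.1, dist = d, link = "offset:0.08",
#'                  seed = 1)
#' @export
simulate_studies <- function(n_studies, theta, dist, alpha_o = 0.05,
                             alpha_r = 0.025,
                             link = power_link("identical"),
                             suppression_odds = 1, seed = NULL,
                             replication = c("mean", "per_study")) {
  if (!is.numeric(n_studies) || n_studies < 1)
    stop("'n_studies' must be at least 1", call. = FALSE)
  n <- as.integer(n_studies)
  .check_prob(theta, "theta")
  .check_prob(alpha_o, "alpha_o", strict = TRUE)
  .check_prob(alpha_r, "alpha_r", strict = TRUE)
  if (!is.numeric(suppression_odds) || suppression_odds < 1)
    stop("'suppression_odds' must be at least 1", call. = FALSE)
  replication <- match.arg(replication)
  link <- as_power_link(link)
  dist <- parse_power_dist(dist)
  if (is.na(dist$mu))
    stop("'dist' must have a resolved mean", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  truth <- runif(n) < theta
  power <- rpowerdist(n, dist)
  positive <- runif(n) < ifelse(truth, power, alpha_o)
  published <- positive | (runif(n) < 1 / suppression_odds)

  if (replication == "per_study") {
    p_rep_true <- replication_power(link, power)
    if (any(p_rep_true > 1))
      stop("replication power exceeds 1 for some studies under this link",
           call. = FALSE)
  } else {
    p_rep_true <- rep(min(replication_power(link, dist$mu), 1), n)
  }
  rep_success <- runif(n) < ifelse(truth, p_rep_true, alpha_r)

  pub_pos <- positive & published
  n_pub_pos <- sum(pub_pos)
  n_replicated <- sum(rep_success & pub_pos)

  # Predictions the empirical rates converge to, by quadrature.
  pool <- pooled_posterior(theta, alpha_o, dist)
  p_total <- prob_positive_total(theta, dist$mu, alpha_o)
  pred_R <- if (replication == "mean") {
    pool * min(replication_power(link, dist$mu), 1) + (1 - pool) * alpha_r
  } else {
    # true findings replicate with their own (selection-weighted) power
    num <- expect_power(dist, function(p) p * replication_power(link, p))
    (theta * num + alpha_r * alpha_o * (1 - theta)) / p_total
  }
  ep <- expected_posterior(theta, alpha_o, dist)

  out <- list(
    n_studies = n,
    config = list(theta = theta, dist = dist, alpha_o = alpha_o,
                  alpha_r = alpha_r, link = link,
                  suppression_odds = suppression_odds,
                  replication = replication, seed = seed),
    n_true = sum(truth),
    n_positive = sum(positive),
    n_published_positive = n_pub_pos,
    n_published_negative = sum(published & !positive),
    n_replicated = n_replicated,
    empirical_positive_rate = mean(positive),
    empirical_reproducibility = if (n_pub_pos > 0) n_replicated / n_pub_pos
                                else NA_real_,
    empirical_posterior_share = if (n_pub_pos > 0)
                                  sum(truth & pub_pos) / n_pub_pos
                                else NA_real_,
    predicted = list(positive_rate = p_total,
                     posterior_share = pool,
                     reproducibility = pred_R),
    closed_form = list(expected_posterior = ep,
                       expected_reproducibility = expected_reproducibility(
                         ep, min(replication_power(link, dist$mu), 1), alpha_r)))
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulated literature (%d studies)\n", x$n_studies))
  cat(sprintf("  true hypotheses      %8d\n", x$n_true))
  cat(sprintf("  positive findings    %8d   rate %.4f (predicted %.4f)\n",
              x$n_positive, x$empirical_positive_rate,
              x$predicted$positive_rate))
  cat(sprintf("  published positives  %8d   true share %.4f (predicted %.4f)\n",
              x$n_published_positive, x$empirical_posterior_share,
              x$predicted$posterior_share))
  cat(sprintf("  replicated           %8d   rate %.4f (predicted %.4f)\n",
              x$n_replicated, x$empirical_reproducibility,
              x$predicted$reproducibility))
  cat(sprintf("  closed-form E[posterior] %.4f, E[R] %.4f\n",
              x$closed_form$expected_posterior,
              x$closed_form$expected_reproducibility))
  invisible(x)
}

#' Bias summary of a simulated literature
#'
#' Evaluates the suppression odds ([bias_odds()]) at the empirical
#' positive-evidence rate of a simulation.
#'
#' @param result A [simulate_studies()] result with at least one positive
#'   finding.
#' @param L Positive share of the published literature.
#' @return A `"bias_result"`.
#' @export
summarize_bias <- function(result, L = 0.9) {
  stopifnot(inherits(result, "sim_result"))
  if (result$n_positive == 0)
    stop("no positive findings: bias odds undefined", call. = FALSE)
  bias_result(result$empirical_positive_rate, L,
              n_published_positive = result$n_published_positive)
}
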