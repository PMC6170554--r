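# Publication-bias metrics: expected positive-evidence rate, suppression
# odds against an observed literature, studies-needed arithmetic, and the
# exact binomial test of literature bias.

#' Expected rate of positive evidence
#'
#' The probability that a single original study yields a positive finding,
#' \eqn{\theta\,\mu + \alpha_o (1-\theta)} with \eqn{\mu} the mean power.
#' Because the positive-evidence identity is linear in power, the mean power
#' is sufficient regardless of its variance.
#'
#' @param theta Prior probability of the tested hypotheses.
#' @param mean_power Mean statistical power of the studies.
#' @param alpha_o Type-1 error rate.
#' @return The expected positive-evidence rate.
#' @examples
#' expected_positive_rate(0.07, 0.66, 0.05)  # ~0.093
#' @export
expected_positive_rate <- function(theta, mean_power, alpha_o = 0.05) {
  prob_positive_total(theta, mean_power, alpha_o)
}

#' Publication-bias odds of suppressing negative evidence
#'
#' Compares the rate at which research *produces* negative evidence with the
#' rate at which the literature *publishes* it. If studies yield positive
#' findings at rate `P` but the literature shows a share `L` of positive
#' findings, the odds of a produced negative result against a published one
#' are
#' \deqn{B = \frac{(1-P)/P}{(1-L)/L},}
#' i.e. negative evidence is observed `B` times for every negative result
#' published. `B = 1` means the literature mirrors production (no
#' suppression). Against the customary 90\% positive literature the formula
#' reduces to \eqn{9(1-P)/P}.
#'
#' @param P Expected positive-evidence rate of the research, in (0,1).
#' @param L Share of positive findings in the published literature, in (0,1).
#' @return The suppression odds \eqn{B > 0}.
#' @examples
#' bias_odds(0.093, 0.90)  # ~88
#' @export
bias_odds <- function(P, L = 0.9) {
  if (!is.numeric(P) || anyNA(P) || any(P <= 0) || any(P >= 1))
    stop("'P' must lie strictly inside (0,1)", call. = FALSE)
  if (!is.numeric(L) || anyNA(L) || any(L <= 0) || any(L >= 1))
    stop("'L' must lie strictly inside (0,1)", call. = FALSE)
  ((1 - P) / P) / ((1 - L) / L)
}

#' Number of studies needed to produce the published positives
#'
#' If positive findings arise at rate `P`, producing `n_published_positive`
#' of them requires `n_published_positive / P` studies in total.
#'
#' @param n_published_positive Count of published positive findings.
#' @param P Expected positive-evidence rate, positive.
#' @return The (real-valued) number of studies needed.
#' @examples
#' studies_needed(97, 0.093)  # ~1043
#' @export
studies_needed <- function(n_published_positive, P) {
  if (!is.numeric(P) || anyNA(P) || any(P <= 0))
    stop("'P' must be positive", call. = FALSE)
  n_published_positive / P
}

#' Exact binomial test of literature bias
#'
#' Tests whether `k` replicated findings out of `n` could have been drawn
#' from a literature with reproducibility `p0`; the alternative of interest
#' is one-sided (reproducibility below `p0`), so the p-value is the exact
#' lower tail \eqn{P(X \le k)} of the Binomial(`n`, `p0`) distribution,
#' computed by [stats::binom.test()].
#'
#' @param k Number of successfully replicated findings. The default, 35, is
#'   `round(0.36 * 97)`: the replication project reported the rate, not the
#'   count.
#' @param n Number of replication attempts.
#' @param p0 Reproducibility expected in an unbiased literature with 90\%
#'   positive findings and identical replication power.
#' @return An object of class `"binomial_bias_test"`: a list with `k`, `n`,
#'   `p0`, `p_value` and the underlying `htest`.
#' @examples
#' binomial_bias_test()          # p far below 1e-15
#' binomial_bias_test(0, 2, 0.9) # p = 0.01
#' @export
binomial_bias_test <- function(k = 35, n = 97, p0 = 0.90) {
  if (k < 0 || k > n) stop("'k' must lie in [0, n]", call. = FALSE)
  .check_prob(p0, "p0", strict = TRUE)
  ht <- binom.test(k, n, p = p0, alternative = "less")
  structure(list(k = k, n = n, p0 = p0, p_value = ht$p.value, htest = ht),
            class = "binomial_bias_test")
}

#' @export
print.binomial_bias_test <- function(x, ...) {
  cat(sprintf("Exact binomial test of literature bias\n  %d/%d replicated vs null reproducibility %.2f\n  one-sided p-value: %.3g\n",
              x$k, x$n, x$p0, x$p_value))
  invisible(x)
}

# Shared constructor for bias summaries (used by the simulator too).
bias_result <- function(P, L = 0.9, n_published_positive = NULL) {
  out <- list(expected_positive_rate = P,
              literature_positive_share = L,
              bias_odds = bias_odds(P, L),
              studies_needed = if (is.null(n_published_positive)) NA_real_
                               else studies_needed(n_published_positive, P))
  class(out) <- "bias_result"
  out
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("Publication-bias summary\n  positive-evidence rate  %.3f\n  literature share        %.2f\n  suppression odds        %.1f\n",
              x$expected_positive_rate, x$literature_positive_share, x$bias_odds))
  if (!is.na(x$studies_needed))
    cat(sprintf("  studies needed          %.0f\n", x$studies_needed))
  invisible(x)
}
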