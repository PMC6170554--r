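# Sweeps over grids of assumed priors, feasibility bounds and envelopes.

#' Log-spaced grid of prior probabilities
#'
#' The default grid used by the sweep tables: `n` log-spaced points on
#' \[`lower`, `upper`\], matching the log-scaled prior axis of the standard
#' figures.
#'
#' @param n Number of grid points.
#' @param lower,upper Grid range, inside (0,1).
#' @return A numeric vector of priors.
#' @export
theta_grid_log <- function(n = 200, lower = 0.025, upper = 0.975) {
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  .check_prob(lower, "lower", strict = TRUE)
  .check_prob(upper, "upper", strict = TRUE)
  if (lower > upper) stop("'lower' must not exceed 'upper'", call. = FALSE)
  if (n == 1) return(lower)
  exp(seq(log(lower), log(upper), length.out = n))
}

#' Sweep the fit over a grid of priors
#'
#' Runs [repro_fit()] for each prior in `theta` and collects the solutions in
#' a data frame (one row per prior; infeasible rows are flagged, not
#' dropped).
#'
#' @param theta Vector of priors, each in (0,1); default [theta_grid_log()].
#' @inheritParams repro_fit
#' @return A data frame of class `"repro_sweep"` with columns `theta`,
#'   `link`, `dist`, `mean_power_original`, `mean_power_replication`,
#'   `expected_posterior`, `expected_positive_rate`, `bias_odds`, `feasible`,
#'   `residual`.
#' @examples
#' sw <- repro_sweep(theta = c(0.05, 0.1, 0.2))
#' sw
#' @export
repro_sweep <- function(theta = theta_grid_log(), R = 0.36, alpha_o = 0.05,
                        alpha_r = 0.025, link = power_link("offset", 0.08),
                        dist = "likely", literature_share = 0.9) {
  if (length(theta) < 1) stop("'theta' grid is empty", call. = FALSE)
  link <- as_power_link(link)
  dist <- parse_power_dist(dist)
  family <- dist; family$mu <- NA_real_
  rows <- lapply(theta, function(th) {
    f <- repro_fit(th, R = R, alpha_o = alpha_o, alpha_r = alpha_r,
                   link = link, dist = dist,
                   literature_share = literature_share)
    data.frame(theta = th, link = format(link),
               dist = format(family),
               mean_power_original = f$mean_power_original,
               mean_power_replication = f$mean_power_replication,
               expected_posterior = f$expected_posterior,
               expected_positive_rate = f$expected_positive_rate,
               bias_odds = f$bias_odds,
               feasible = f$feasible,
               residual = f$residual,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "R") <- R
  class(out) <- c("repro_sweep", "data.frame")
  out
}

#' @export
print.repro_sweep <- function(x, ...) {
  cat(sprintf("Prior sweep (%d priors, R = %g, %d feasible)\n",
              nrow(x), attr(x, "R"), sum(x$feasible)))
  print.data.frame(x, digits = 4, row.names = FALSE, ...)
  invisible(x)
}

#' Smallest feasible prior for a scenario
#'
#' Bisects (to `tol`) for the smallest prior at which [repro_fit()] has a
#' feasible solution. A reproducibility rate cannot be explained by priors
#' below this bound without implying better-than-perfect power somewhere in
#' the system.
#'
#' @inheritParams repro_fit
#' @param tol Bisection tolerance on the prior.
#' @param lower Lower edge of the searched prior range.
#' @return The smallest feasible prior. If the scenario is feasible at
#'   `lower` already, returns `lower` with attribute
#'   `feasible_at_lower = TRUE`.
#' @examples
#' feasibility_bound(link = "identical", dist = "zero")  # ~0.0255
#' @export
feasibility_bound <- function(R = 0.36, alpha_o = 0.05, alpha_r = 0.025,
                              link = power_link("identical"), dist = "zero",
                              tol = 1e-4, lower = 1e-4) {
  link <- as_power_link(link)
  dist <- parse_power_dist(dist)
  ok <- function(th) repro_fit(th, R = R, alpha_o = alpha_o, alpha_r = alpha_r,
                               link = link, dist = dist)$feasible
  if (!ok(0.5))
    stop("scenario is infeasible even at theta = 0.5", call. = FALSE)
  if (ok(lower)) {
    return(structure(lower, feasible_at_lower = TRUE))
  }
  lo <- lower; hi <- 0.5
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ok(mid)) hi <- mid else lo <- mid
  }
  hi
}

# Normalize a variant into a (link, dist) pair.
.as_variant <- function(v) {
  if (is.character(v) && length(v) == 1)
    stop("string variants are not supported; give list(link=, dist=)",
         call. = FALSE)
  if (!is.list(v) || is.null(v$link) || is.null(v$dist))
    stop("each variant must be a list with elements 'link' and 'dist'",
         call. = FALSE)
  list(link = as_power_link(v$link), dist = parse_power_dist(v$dist))
}

#' Envelope of sweeps across scenario variants
#'
#' Sweeps each (link, distribution) variant over the same prior grid and
#' reports, per prior, the minimum and maximum of each solved quantity across
#' the feasible variants — the shaded uncertainty bands of the standard
#' figures. A prior at which every variant is infeasible is flagged.
#'
#' @inheritParams repro_sweep
#' @param variants A list of variants, each `list(link =, dist =)`.
#' @return A data frame of class `"repro_envelope"`: per prior, columns
#'   `<field>_min` / `<field>_max` for each solved field, plus `n_feasible`.
#' @examples
#' ev <- envelope(theta = c(0.05, 0.2),
#'                variants = list(list(link = "offset:0.06", dist = "likely"),
#'                                list(link = "offset:0.10", dist = "likely")))
#' @export
envelope <- function(theta = theta_grid_log(), variants, R = 0.36,
                     alpha_o = 0.05, alpha_r = 0.025, literature_share = 0.9) {
  if (length(variants) < 1) stop("'variants' is empty", call. = FALSE)
  variants <- lapply(variants, .as_variant)
  sweeps <- lapply(variants, function(v)
    repro_sweep(theta = theta, R = R, alpha_o = alpha_o, alpha_r = alpha_r,
                link = v$link, dist = v$dist,
                literature_share = literature_share))
  fields <- c("mean_power_original", "mean_power_replication",
              "expected_posterior", "expected_positive_rate", "bias_odds")
  rows <- lapply(seq_along(theta), function(i) {
    vals <- lapply(sweeps, function(s) s[i, , drop = FALSE])
    feas <- vapply(vals, function(r) isTRUE(r$feasible), logical(1))
    row <- data.frame(theta = theta[i], n_feasible = sum(feas))
    for (f in fields) {
      v <- vapply(vals[feas], function(r) r[[f]], numeric(1))
      row[[paste0(f, "_min")]] <- if (length(v)) min(v) else NA_real_
      row[[paste0(f, "_max")]] <- if (length(v)) max(v) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "R") <- R
  class(out) <- c("repro_envelope", "data.frame")
  out
}

#' Plot a prior sweep
#'
#' Four-panel base-graphics display of a sweep: expected original power,
#' expected posterior, expected positive-evidence rate and bias odds against
#' the assumed prior (log-scaled prior axis; log-scaled odds).
#'
#' @param x A [repro_sweep()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.repro_sweep <- function(x, ...) {
  ok <- x$feasible
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panel <- function(y, ylab, log = "x") {
    graphics::plot(x$theta[ok], y[ok], type = "l", log = log,
                   xlab = expression(theta), ylab = ylab, ...)
  }
  panel(x$mean_power_original, "expected power (original)")
  panel(x$expected_posterior, "expected posterior")
  panel(x$expected_positive_rate, "expected positive rate")
  panel(x$bias_odds, "bias odds", log = "xy")
  invisible(x)
}
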