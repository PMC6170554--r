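# Distributions of per-study statistical power.
#
# Power is modelled on [floor, 1] with floor = alpha by default: a two-sided
# NHST test rejects with probability at least its level alpha, so per-study
# power cannot fall below it. Internally power = floor + (1 - floor) * X with
# X a point mass, a Beta variable, or a two-component Beta mixture on [0,1].
#
# The single shape parameter s is attached to the type-2-error side: the
# density of beta = 1 - X is Beta(s, s2) with s2 derived from the mean, so X
# itself is Beta(second_shape(s, 1 - m), s) with m the mean of X.

#' Second shape parameter of a Beta distribution from its mean
#'
#' A Beta distribution with first shape `s` has mean `mu` exactly when its
#' second shape is `s * (1 - mu) / mu`.
#'
#' @param s First shape parameter, positive.
#' @param mu Desired mean, strictly inside (0,1).
#' @return The second shape parameter.
#' @examples
#' second_shape(1, 0.25)  # 3
#' @export
second_shape <- function(s, mu) {
  if (!is.numeric(s) || anyNA(s) || any(s <= 0))
    stop("'s' must be positive", call. = FALSE)
  if (!is.numeric(mu) || anyNA(mu) || any(mu <= 0) || any(mu >= 1))
    stop("'mu' must lie strictly inside (0,1)", call. = FALSE)
  s * (1 - mu) / mu
}

#' Weight of the low-power component of a two-point mixture
#'
#' For a mixture of two components with fixed means `m_lo < m_hi`, the weight
#' on the low component that gives overall mean `mu` is
#' `(m_hi - mu) / (m_hi - m_lo)`. The weight leaves \[0,1\] exactly when `mu`
#' falls outside \[`m_lo`, `m_hi`\]; that is reported as `NA` with a warning
#' rather than an error so that sweeps can flag infeasible rows.
#'
#' @param mu Overall mean.
#' @param m_lo,m_hi Fixed component means, `m_lo < m_hi`.
#' @return The mixture weight on the low component, or `NA` if `mu` is not
#'   bracketed by the component means.
#' @examples
#' mixture_weight(0.525, 0.145, 0.905)  # 0.5
#' @export
mixture_weight <- function(mu, m_lo, m_hi) {
  if (!(m_lo < m_hi)) stop("'m_lo' must be smaller than 'm_hi'", call. = FALSE)
  w <- (m_hi - mu) / (m_hi - m_lo)
  bad <- w < 0 | w > 1
  if (any(bad)) {
    warning("mean outside the component means: mixture infeasible", call. = FALSE)
    w[bad] <- NA_real_
  }
  w
}

#' Distribution of per-study statistical power
#'
#' Constructs a distribution over the power of individual studies, used when
#' integrating the posterior probability over between-study variance in
#' power. Three families are supported:
#'
#' * `"point"` — all studies share one power value (zero variance);
#' * `"beta"` — a Beta distribution with a single free shape parameter `s`;
#' * `"bimodal"` — a weighted average of two Beta components with fixed means,
#'   describing a literature in which most studies have either very low or
#'   very high power, as meta-meta-analytic surveys indicate.
#'
#' Power lives on \[`floor`, 1\] with `floor = 0.05` by default: a test
#' rejects with probability at least its level, so power cannot fall below
#' \eqn{\alpha}. Writing power \eqn{= \alpha + (1-\alpha) X}, the families
#' above describe \eqn{X} on \[0,1\]. The shape `s` is the first shape
#' parameter of the density of the type-2 error rate \eqn{1 - X}; its second
#' shape is derived from the mean via [second_shape()]. The default bimodal
#' component means, `0.145` and `0.905` on the power scale, are
#' \eqn{X = 0.10} and \eqn{X = 0.90}; the extreme-variance preset uses
#' `0.0975`/`0.9525`, i.e. \eqn{X = 0.05}/\eqn{X = 0.95}.
#'
#' The mean `mu` may be left `NA` to describe a family whose mean is to be
#' solved for (as [repro_fit()] does); most methods require a resolved mean.
#'
#' @param family `"point"`, `"beta"` or `"bimodal"`.
#' @param mu Mean power, in (`floor`, 1); `NA` for a free-mean family.
#' @param s Shape parameter of the beta family.
#' @param s_lo,s_hi Component shapes of the bimodal family (low-, high-power).
#' @param m_lo,m_hi Component means of the bimodal family on the power scale.
#' @param floor Lower end of the power scale, normally the type-1 error rate
#'   of the original studies. Set to 0 for an unfloored distribution on \[0,1\].
#' @return An object of class `"power_dist"`.
#' @examples
#' power_dist("beta", mu = 0.59, s = 0.5)
#' power_dist("bimodal", mu = 0.5)                  # moderate bimodal
#' dist_preset("extreme", mu = 0.5)                 # 5th/95th-percentile bimodal
#' @seealso [dist_preset()], [parse_power_dist()], [dist_variance()]
#' @export
power_dist <- function(family = c("point", "beta", "bimodal"), mu = NA_real_,
                       s = 0.5, s_lo = 1, s_hi = 2,
                       m_lo = 0.145, m_hi = 0.905, floor = 0.05) {
  family <- match.arg(family)
  if (!is.numeric(floor) || floor < 0 || floor >= 1)
    stop("'floor' must lie in [0,1)", call. = FALSE)
  if (family == "point") floor <- 0  # an atom needs no rescaled support
  if (family == "beta" && (!is.numeric(s) || s <= 0))
    stop("'s' must be positive", call. = FALSE)
  if (family == "bimodal") {
    if (s_lo <= 0 || s_hi <= 0) stop("component shapes must be positive", call. = FALSE)
    if (!(floor <= m_lo && m_lo < m_hi && m_hi <= 1))
      stop("component means must satisfy floor <= m_lo < m_hi <= 1", call. = FALSE)
  }
  d <- structure(list(family = family, mu = NA_real_, s = s,
                      s_lo = s_lo, s_hi = s_hi, m_lo = m_lo, m_hi = m_hi,
                      floor = floor),
                 class = "power_dist")
  if (!is.na(mu)) d <- set_mean(d, mu) else d
}

# Resolve the free mean of a family; validates feasibility for the mixture.
set_mean <- function(dist, mu) {
  stopifnot(inherits(dist, "power_dist"))
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu))
    stop("'mu' must be a single number", call. = FALSE)
  if (mu <= dist$floor || mu > 1)
    stop(sprintf("'mu' must lie in (%g, 1]", dist$floor), call. = FALSE)
  if (dist$family != "point" && mu == 1)
    stop("'mu' = 1 requires the point family", call. = FALSE)
  if (dist$family == "bimodal" && (mu < dist$m_lo || mu > dist$m_hi))
    stop("bimodal mean outside the component means: infeasible", call. = FALSE)
  dist$mu <- mu
  dist
}

# Mean of X = (power - floor) / (1 - floor).
.x_mean <- function(dist, mu = dist$mu) (mu - dist$floor) / (1 - dist$floor)

# Beta shapes of the X-scale components, plus weights. The shape s sits on
# the type-2-error side: X_c ~ Beta(second_shape(s, 1 - m), s).
.components <- function(dist) {
  stopifnot(!is.na(dist$mu))
  side <- function(m, s) c(second_shape(s, 1 - m), s)
  if (dist$family == "beta") {
    m <- .x_mean(dist)
    ab <- side(m, dist$s)
    list(w = 1, a = ab[1], b = ab[2])
  } else if (dist$family == "bimodal") {
    m_lo <- .x_mean(dist, dist$m_lo)
    m_hi <- .x_mean(dist, dist$m_hi)
    w <- mixture_weight(.x_mean(dist), m_lo, m_hi)
    lo <- side(m_lo, dist$s_lo)
    hi <- side(m_hi, dist$s_hi)
    list(w = c(w, 1 - w), a = c(lo[1], hi[1]), b = c(lo[2], hi[2]))
  } else stop("point family has no Beta components", call. = FALSE)
}

#' @export
mean.power_dist <- function(x, ...) x$mu

#' Variance of a power distribution
#'
#' Closed form: zero for a point mass; for a Beta component with shapes
#' \eqn{(a,b)} the X-scale variance is \eqn{m(1-m)/(a+b+1)}; mixture variance
#' by the usual decomposition. The X-scale variance is rescaled by
#' \eqn{(1-floor)^2} to the power scale.
#'
#' @param dist A resolved [power_dist()].
#' @return The variance of per-study power.
#' @examples
#' dist_variance(power_dist("beta", mu = 0.35, s = 0.5))
#' @export
dist_variance <- function(dist) {
  stopifnot(inherits(dist, "power_dist"))
  if (is.na(dist$mu)) stop("distribution mean is unresolved", call. = FALSE)
  if (dist$family == "point") return(0)
  cp <- .components(dist)
  m <- cp$a / (cp$a + cp$b)
  v <- m * (1 - m) / (cp$a + cp$b + 1)
  vx <- sum(cp$w * (v + m^2)) - .x_mean(dist)^2
  (1 - dist$floor)^2 * vx
}

#' @describeIn power_dist Density of per-study power at the points `at`.
#'   Zero outside (`floor`, 1); the point family has no finite density
#'   (`Inf` at its atom).
#' @param x A `power_dist` object.
#' @param at Numeric vector of power values at which to evaluate the density.
#' @param ... Unused.
#' @export
density.power_dist <- function(x, at, ...) {
  if (is.na(x$mu)) stop("distribution mean is unresolved", call. = FALSE)
  if (x$family == "point") {
    out <- ifelse(at == x$mu, Inf, 0)
    return(out)
  }
  cp <- .components(x)
  sc <- 1 - x$floor
  u <- (at - x$floor) / sc
  out <- numeric(length(at))
  inside <- u >= 0 & u <= 1
  for (i in seq_along(cp$w))
    out[inside] <- out[inside] + cp$w[i] * dbeta(u[inside], cp$a[i], cp$b[i]) / sc
  out
}

# Random draws of per-study power. RNG order: one uniform vector for the
# mixture component, then one rbeta call (so seeds are portable).
rpowerdist <- function(n, dist) {
  if (is.na(dist$mu)) stop("distribution mean is unresolved", call. = FALSE)
  if (dist$family == "point") return(rep(dist$mu, n))
  cp <- .components(dist)
  if (length(cp$w) == 1L) {
    x <- rbeta(n, cp$a, cp$b)
  } else {
    lo <- runif(n) < cp$w[1]
    x <- rbeta(n, ifelse(lo, cp$a[1], cp$a[2]), ifelse(lo, cp$b[1], cp$b[2]))
  }
  dist$floor + (1 - dist$floor) * x
}

#' Named power-distribution presets
#'
#' The variance assumptions used by the standard analyses:
#' `"zero"` (point mass), `"likely"` (beta, s = 1/2, matching the variance of
#' power observed across published meta-meta-analyses), `"alt_small"` (beta,
#' s = 1), `"alt_large"` (bimodal, means 0.145/0.905, shapes 1 and 2) and
#' `"extreme"` (bimodal, means 0.0975/0.9525, both shapes 1).
#'
#' @param name Preset name.
#' @param mu Optional mean power; `NA` leaves the mean free.
#' @param floor Lower end of the power scale.
#' @return A [power_dist()].
#' @examples
#' dist_preset("likely")
#' @export
dist_preset <- function(name = c("zero", "likely", "alt_small", "alt_large",
                                 "extreme"),
                        mu = NA_real_, floor = 0.05) {
  name <- match.arg(name)
  switch(name,
    zero      = power_dist("point", mu, floor = floor),
    likely    = power_dist("beta", mu, s = 0.5, floor = floor),
    alt_small = power_dist("beta", mu, s = 1, floor = floor),
    alt_large = power_dist("bimodal", mu, s_lo = 1, s_hi = 2,
                           m_lo = floor + (1 - floor) * 0.10,
                           m_hi = 1 - (1 - floor) * 0.10, floor = floor),
    extreme   = power_dist("bimodal", mu, s_lo = 1, s_hi = 1,
                           m_lo = floor + (1 - floor) * 0.05,
                           m_hi = 1 - (1 - floor) * 0.05, floor = floor))
}

#' Parse a power-distribution spec string
#'
#' Accepts preset names (see [dist_preset()]) and compact specs:
#' `"point"`, `"beta:<s>"`, `"bimodal:<s_lo>,<s_hi>:<m_lo>,<m_hi>"` with the
#' component means on the power scale.
#'
#' @param spec A string, or an existing `power_dist` (returned unchanged).
#' @param mu Optional mean power.
#' @param floor Lower end of the power scale.
#' @return A [power_dist()].
#' @examples
#' parse_power_dist("beta:0.5")
#' parse_power_dist("bimodal:1,1:0.0975,0.9525")
#' @export
parse_power_dist <- function(spec, mu = NA_real_, floor = 0.05) {
  if (inherits(spec, "power_dist")) {
    if (!is.na(mu)) spec <- set_mean(spec, mu)
    return(spec)
  }
  if (!is.character(spec) || length(spec) != 1)
    stop("cannot interpret distribution spec", call. = FALSE)
  if (spec %in% c("zero", "likely", "alt_small", "alt_large", "extreme"))
    return(dist_preset(spec, mu, floor))
  if (spec == "point") return(power_dist("point", mu, floor = floor))
  if (grepl("^beta:", spec))
    return(power_dist("beta", mu, s = as.numeric(sub("^beta:", "", spec)),
                      floor = floor))
  if (grepl("^bimodal:", spec)) {
    parts <- strsplit(sub("^bimodal:", "", spec), ":")[[1]]
    if (length(parts) != 2)
      stop("bimodal spec must be 'bimodal:<s_lo>,<s_hi>:<m_lo>,<m_hi>'", call. = FALSE)
    ss <- as.numeric(strsplit(parts[1], ",")[[1]])
    ms <- as.numeric(strsplit(parts[2], ",")[[1]])
    return(power_dist("bimodal", mu, s_lo = ss[1], s_hi = ss[2],
                      m_lo = ms[1], m_hi = ms[2], floor = floor))
  }
  stop(sprintf("unknown distribution spec '%s'", spec), call. = FALSE)
}

#' @export
format.power_dist <- function(x, ...) {
  base <- switch(x$family,
    point   = "point",
    beta    = sprintf("beta:%g", x$s),
    bimodal = sprintf("bimodal:%g,%g:%g,%g", x$s_lo, x$s_hi, x$m_lo, x$m_hi))
  if (!is.na(x$mu)) sprintf("%s (mean %.4g)", base, x$mu) else base
}

#' @export
print.power_dist <- function(x, ...) {
  cat("Per-study power distribution:", format(x), "\n")
  cat("  power scale: [", x$floor, ", 1]\n", sep = "")
  if (!is.na(x$mu) && x$family != "point")
    cat(sprintf("  variance: %.4f\n", dist_variance(x)))
  invisible(x)
}
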