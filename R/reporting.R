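# Scenario presets, sweep-table reproduction and JSON run configuration.

#' Named scenario presets
#'
#' Each preset names a (power link, power distribution) pair used by the
#' standard analyses:
#'
#' * `likely_low`, `likely_mid`, `likely_high` — replication power 6, 8 or 10
#'   points above original power, Beta (s = 1/2) variance;
#' * `alt_small`, `alt_large` — the likely offsets' midpoint with the
#'   smaller-variance Beta (s = 1) or larger-variance bimodal distribution;
#' * `extreme` — midpoint offset with the extreme-variance bimodal;
#' * `zero_variance` — midpoint offset with a point mass;
#' * `outer_lower`, `outer_upper` — the conservative outer corners: perfect
#'   replication power with zero variance, and identical power with extreme
#'   variance.
#'
#' @param name Preset name.
#' @return A list with elements `link` (a [power_link()]) and `dist`
#'   (a free-mean [power_dist()]).
#' @examples
#' scenario_preset("likely_mid")
#' @export
scenario_preset <- function(name = c("likely_low", "likely_mid", "likely_high",
                                     "alt_small", "alt_large", "extreme",
                                     "zero_variance", "outer_lower",
                                     "outer_upper")) {
  name <- match.arg(name)
  mid <- power_link("offset", 0.08)
  switch(name,
    likely_low    = list(link = power_link("offset", 0.06), dist = dist_preset("likely")),
    likely_mid    = list(link = mid, dist = dist_preset("likely")),
    likely_high   = list(link = power_link("offset", 0.10), dist = dist_preset("likely")),
    alt_small     = list(link = mid, dist = dist_preset("alt_small")),
    alt_large     = list(link = mid, dist = dist_preset("alt_large")),
    extreme       = list(link = mid, dist = dist_preset("extreme")),
    zero_variance = list(link = mid, dist = dist_preset("zero")),
    outer_lower   = list(link = power_link("perfect"), dist = dist_preset("zero")),
    outer_upper   = list(link = power_link("identical"), dist = dist_preset("extreme")))
}

# Variant lists behind the shaded bands of the main sweep figure.
.band_variants <- function(band) {
  cross <- function(links, dists)
    unlist(lapply(links, function(l) lapply(dists, function(d)
      list(link = l, dist = d))), recursive = FALSE)
  offsets <- list(power_link("offset", 0.06), power_link("offset", 0.10))
  switch(band,
    likely        = cross(offsets, list(dist_preset("likely"))),
    alternative   = cross(offsets, list(dist_preset("alt_small"),
                                        dist_preset("alt_large"))),
    extreme       = cross(offsets, list(dist_preset("extreme"))),
    zero_variance = cross(offsets, list(dist_preset("zero"))),
    outer         = cross(list(power_link("identical"), power_link("perfect")),
                          list(dist_preset("zero"), dist_preset("extreme"))),
    stop(sprintf("unknown band '%s'", band), call. = FALSE))
}

#' Reproduce the prior-sweep tables (bands over assumed priors)
#'
#' Computes, for a fixed replication rate, the envelope of solutions over
#' each named band of scenario variants — the machine-readable counterpart of
#' the four-panel sweep figure — and writes one CSV per band.
#'
#' @param out_dir Directory for the CSV files (created if needed); `NULL`
#'   skips writing.
#' @param R Replication rate.
#' @param theta Prior grid; default 200 log-spaced points on
#'   \[0.025, 0.975\].
#' @param bands Band names: any of `"likely"`, `"alternative"`, `"extreme"`,
#'   `"zero_variance"`, `"outer"`.
#' @param literature_share Positive share of the published literature.
#' @return Invisibly, a named list of [envelope()] tables.
#' @examples
#' tabs <- run_figure2(out_dir = NULL, theta = c(0.05, 0.2),
#'                     bands = "likely")
#' @export
run_figure2 <- function(out_dir = "figure2", R = 0.36,
                        theta = theta_grid_log(),
                        bands = c("likely", "alternative", "extreme",
                                  "zero_variance", "outer"),
                        literature_share = 0.9) {
  if (length(theta) < 1) stop("'theta' grid is empty", call. = FALSE)
  bands <- match.arg(bands, several.ok = TRUE)
  tabs <- lapply(bands, function(b)
    envelope(theta = theta, variants = .band_variants(b), R = R,
             literature_share = literature_share))
  names(tabs) <- bands
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (b in bands) {
      path <- file.path(out_dir, sprintf("fig2_%s.csv", b))
      write.csv(as.data.frame(tabs[[b]]), path, row.names = FALSE)
    }
  }
  invisible(tabs)
}

#' Reproduce the sweep tables across alternative replication rates
#'
#' Sweeps the likely-midpoint scenario (offset +0.08, Beta s = 1/2) over the
#' prior grid for each replication rate in `R` — the point estimate and the
#' bounds of its 50/75/95\% confidence intervals — and writes one CSV per
#' rate.
#'
#' @param out_dir Directory for the CSV files; `NULL` skips writing.
#' @param R Vector of replication rates.
#' @param theta Prior grid.
#' @param literature_share Positive share of the published literature.
#' @return Invisibly, a named list of [repro_sweep()] tables.
#' @export
run_figure3 <- function(out_dir = "figure3",
                        R = c(0.27, 0.30, 0.32, 0.36, 0.40, 0.42, 0.46),
                        theta = theta_grid_log(),
                        literature_share = 0.9) {
  if (length(theta) < 1) stop("'theta' grid is empty", call. = FALSE)
  preset <- scenario_preset("likely_mid")
  tabs <- lapply(R, function(r)
    repro_sweep(theta = theta, R = r, link = preset$link, dist = preset$dist,
                literature_share = literature_share))
  names(tabs) <- sprintf("R%.2f", R)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(tabs)) {
      path <- file.path(out_dir, sprintf("fig3_%s.csv", nm))
      write.csv(as.data.frame(tabs[[nm]]), path, row.names = FALSE)
    }
  }
  invisible(tabs)
}

#' Load a run configuration from JSON
#'
#' Reads a JSON configuration for the reporting functions. Recognized fields:
#' `preset` (a [scenario_preset()] name), `R` (scalar or vector), `theta_min`,
#' `theta_max`, `theta_points`, `literature_share`, `out_dir`, `seed`.
#' Unknown presets and malformed fields are rejected at load time.
#'
#' @param path Path to a JSON file.
#' @return A list with validated entries (missing fields get defaults).
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$preset)) {
    valid <- c("likely_low", "likely_mid", "likely_high", "alt_small",
               "alt_large", "extreme", "zero_variance", "outer_lower",
               "outer_upper")
    if (!all(cfg$preset %in% valid))
      stop(sprintf("unknown preset name(s): %s",
                   paste(setdiff(cfg$preset, valid), collapse = ", ")),
           call. = FALSE)
  }
  defaults <- list(preset = "likely_mid", R = 0.36, theta_min = 0.025,
                   theta_max = 0.975, theta_points = 200,
                   literature_share = 0.9, out_dir = ".", seed = 1L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (any(cfg$R <= 0 | cfg$R >= 1)) stop("'R' must lie in (0,1)", call. = FALSE)
  if (cfg$theta_points < 1) stop("'theta_points' must be at least 1", call. = FALSE)
  .check_prob(cfg$theta_min, "theta_min", strict = TRUE)
  .check_prob(cfg$theta_max, "theta_max", strict = TRUE)
  cfg
}
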