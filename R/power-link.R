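# Linkage between original-study and replication-study power.

#' Power linkage between original and replication studies
#'
#' Replication studies in a direct-replication project are usually designed
#' with larger samples than the originals, so their power is at least as
#' high. Three linkages bracket the possibilities:
#'
#' * `"identical"` — replication power equals original power (lower bound);
#' * `"perfect"` — replication power is 1 (upper bound);
#' * `"offset"` — replication power is original power plus `delta`
#'   (e.g. the 6--10 percentage points implied by the median sample sizes of
#'   the OSC replications).
#'
#' @param kind One of `"identical"`, `"perfect"`, `"offset"`.
#' @param delta Additive power offset in \[0,1\]; only used by `"offset"`.
#' @return An object of class `"power_link"`.
#' @examples
#' power_link("offset", 0.08)
#' as_power_link("offset:0.06")
#' @export
power_link <- function(kind = c("identical", "perfect", "offset"), delta = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta < 0 || delta > 1)
    stop("'delta' must be a single value in [0,1]", call. = FALSE)
  if (kind == "identical") delta <- 0
  structure(list(kind = kind, delta = delta), class = "power_link")
}

#' @rdname power_link
#' @param x A `power_link`, or a string spec: `"identical"`, `"perfect"` or
#'   `"offset:<delta>"`.
#' @export
as_power_link <- function(x) {
  if (inherits(x, "power_link")) return(x)
  if (!is.character(x) || length(x) != 1)
    stop("cannot interpret 'link'; give a power_link() or a string spec",
         call. = FALSE)
  if (x %in% c("identical", "perfect")) return(power_link(x))
  if (grepl("^offset:", x))
    return(power_link("offset", as.numeric(sub("^offset:", "", x))))
  stop(sprintf("unknown power link '%s'", x), call. = FALSE)
}

# Replication power implied by the link at original (mean) power mu.
replication_power <- function(link, mu) {
  switch(link$kind,
         identical = mu,
         perfect   = rep(1, length(mu)),
         offset    = mu + link$delta)
}

#' @export
format.power_link <- function(x, ...) {
  switch(x$kind,
         identical = "identical",
         perfect = "perfect",
         offset = sprintf("offset:%g", x$delta))
}

#' @export
print.power_link <- function(x, ...) {
  cat("Power link:", format(x), "\n")
  invisible(x)
}
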