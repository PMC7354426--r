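# Cord specification and elongation arithmetic.

# Mid-range rest lengths used when a scenario does not state one; the two
# commercial cord types come in narrow length ranges.
.REST_RANGE <- list(thick = c(0.605, 0.630), thin = c(0.620, 0.655))
.REST_DEFAULT <- list(thick = 0.6175, thin = 0.6375)

#' Specify an elastic cord (expander)
#'
#' A cord is described by its type (`"thick"` or `"thin"`) and its rest
#' length: the straight-line length at zero force, measured before use.
#' Commercial cords of each type fall in a narrow length band
#' (thick 0.605--0.630 m, thin 0.620--0.655 m); a rest length outside the
#' band for its type is accepted with a warning.
#'
#' @param kind `"thick"` or `"thin"`.
#' @param rest_length_m Rest (zero-force) length in metres. Defaults to the
#'   mid-range length for the cord type (0.6175 m thick, 0.6375 m thin).
#' @return An object of class `cord_spec` with fields `kind` and
#'   `rest_length_m`.
#' @examples
#' cord_spec("thick")
#' cord_spec("thin", rest_length_m = 0.62)
#' @export
cord_spec <- function(kind = c("thick", "thin"), rest_length_m = NULL) {
  kind <- match.arg(kind)
  if (is.null(rest_length_m)) rest_length_m <- .REST_DEFAULT[[kind]]
  stopifnot(is.numeric(rest_length_m), length(rest_length_m) == 1L)
  if (!is.finite(rest_length_m) || rest_length_m <= 0) {
    stop("`rest_length_m` must be a positive finite length in metres",
         call. = FALSE)
  }
  rng <- .REST_RANGE[[kind]]
  if (rest_length_m < rng[1] || rest_length_m > rng[2]) {
    warning(sprintf(
      "rest length %.4f m is outside the usual %s-cord range [%.3f, %.3f] m",
      rest_length_m, kind, rng[1], rng[2]), call. = FALSE)
  }
  structure(list(kind = kind, rest_length_m = rest_length_m),
            class = "cord_spec")
}

#' @export
print.cord_spec <- function(x, ...) {
  cat(sprintf("<cord_spec> %s cord, rest length %.4f m\n",
              x$kind, x$rest_length_m))
  invisible(x)
}

#' Cord elongation as percent of rest length
#'
#' Elongation is expressed as a percentage of the cord's rest length. A
#' stretched length shorter than the rest length means a slack cord and
#' returns 0 (a cord cannot be compressed).
#'
#' @param spec A [cord_spec()].
#' @param stretched_length_m Current anchor-to-belt straight-line length in
#'   metres (vectorised).
#' @return Elongation in percent, clamped below at 0.
#' @examples
#' elongation_pct(cord_spec("thick", 0.605), 0.855) # 41.32
#' @export
elongation_pct <- function(spec, stretched_length_m) {
  stopifnot(inherits(spec, "cord_spec"), is.numeric(stretched_length_m))
  if (any(!is.finite(stretched_length_m)) || any(stretched_length_m <= 0)) {
    stop("`stretched_length_m` must be positive and finite", call. = FALSE)
  }
  pmax(0, 100 * (stretched_length_m - spec$rest_length_m) / spec$rest_length_m)
}
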