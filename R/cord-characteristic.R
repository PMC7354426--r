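# Sum-of-sines cord tension characteristic: construction, evaluation,
# working range, parallel use, and JSON serialisation.

#' Build a three-term sum-of-sines cord characteristic
#'
#' Tension as a function of elongation is modelled as
#' \deqn{T(x) = \sum_{k=1}^{3} a_k \sin(b_k x + c_k)}
#' with `x` the elongation in percent of rest length on the fitted domain
#' \[0, 100\]. Exactly three terms are used. Evaluated tension is floored at
#' 0 N: a cord transmits tension only.
#'
#' @param spec A [cord_spec()].
#' @param amplitudes,frequencies,phases Numeric vectors of length 3:
#'   amplitudes `a_k` in newtons, angular frequencies `b_k` in radians per
#'   elongation percent, phases `c_k` in radians.
#' @param r_squared Coefficient of determination of the originating fit, or
#'   `NA` for analytically constructed characteristics.
#' @return An object of class `cord_characteristic`.
#' @seealso [tension()], [fit_sum_of_sines()], [working_range()]
#' @export
cord_characteristic <- function(spec, amplitudes, frequencies, phases,
                                r_squared = NA_real_) {
  stopifnot(inherits(spec, "cord_spec"))
  if (length(amplitudes) != 3L || length(frequencies) != 3L ||
      length(phases) != 3L) {
    stop("a sum-of-sines characteristic has exactly 3 terms", call. = FALSE)
  }
  co <- c(amplitudes, frequencies, phases)
  if (!all(is.finite(co))) {
    stop("characteristic coefficients must be finite", call. = FALSE)
  }
  if (!is.na(r_squared) && (r_squared > 1 + 1e-12)) {
    stop("`r_squared` cannot exceed 1", call. = FALSE)
  }
  obj <- structure(list(
    spec = spec,
    amplitudes = as.numeric(amplitudes),
    frequencies = as.numeric(frequencies),
    phases = as.numeric(phases),
    domain = c(0, 100),
    r_squared = as.numeric(r_squared)
  ), class = "cord_characteristic")
  # evaluability over the whole domain is part of the contract
  if (!all(is.finite(.sos_eval(obj, seq(0, 100, by = 1))))) {
    stop("characteristic is not finite over the domain [0, 100]%",
         call. = FALSE)
  }
  obj
}

# raw sum of sines, no floor
.sos_eval <- function(char, x) {
  out <- numeric(length(x))
  for (k in 1:3) {
    out <- out + char$amplitudes[k] *
      sin(char$frequencies[k] * x + char$phases[k])
  }
  out
}

#' Evaluate cord tension at a given elongation
#'
#' Evaluates the three-term sum-of-sines model and floors the result at 0 N.
#' The model is only valid on its fitted domain: elongations above 100%
#' raise an error rather than extrapolate. Negative elongations describe a
#' slack cord and return 0 N with a warning.
#'
#' @param char A [cord_characteristic()].
#' @param elongation_pct Elongation in percent of rest length (vectorised).
#' @return Tension in newtons, never negative.
#' @examples
#' ch <- cord_characteristic(cord_spec("thick"), c(10, 0, 0),
#'                           c(pi / 200, 1, 1), c(0, 0, 0))
#' tension(ch, 100) # a sin(pi/2) peak: 10 N
#' @export
tension <- function(char, elongation_pct) {
  stopifnot(inherits(char, "cord_characteristic"),
            is.numeric(elongation_pct))
  if (any(elongation_pct > char$domain[2])) {
    stop(sprintf(
      "elongation %.4g%% is outside the fitted domain [%g, %g]%%",
      max(elongation_pct), char$domain[1], char$domain[2]), call. = FALSE)
  }
  x <- elongation_pct
  if (any(x < 0)) {
    warning("negative elongation treated as a slack cord (0 N)",
            call. = FALSE)
    x <- pmax(x, 0)
  }
  t <- pmax(0, .sos_eval(char, x))
  t[elongation_pct < 0] <- 0
  t
}

#' Combined tension of cords routed in parallel
#'
#' Two or more cords run together along the same anchor-to-belt path share
#' one elongation; their tensions add.
#'
#' @param chars List of [cord_characteristic()] objects.
#' @param elongation_pct Shared elongation in percent.
#' @return Total tension in newtons.
#' @export
parallel_tension <- function(chars, elongation_pct) {
  if (!is.list(chars) || length(chars) == 0L) {
    stop("`chars` must be a non-empty list of cord characteristics",
         call. = FALSE)
  }
  Reduce(`+`, lapply(chars, tension, elongation_pct = elongation_pct))
}

#' Usable (strictly increasing) elongation range of a characteristic
#'
#' The practically desirable elongation band for these cords is 20--80% of
#' rest length. Within that band the fitted model should be strictly
#' increasing so that tension is controllable by elongation. This returns
#' the maximal sub-interval of \[20, 80\] starting at 20% on which the
#' evaluated tension is strictly increasing, scanned on a dense 0.1% grid.
#' A characteristic that never increases in the band is degenerate: a
#' warning is issued and an empty (zero-length) range returned.
#'
#' @param char A [cord_characteristic()].
#' @param step Grid step in percent for the monotonicity scan.
#' @return Numeric vector `c(lo, hi)` in percent; `hi == lo` for an empty
#'   range.
#' @export
working_range <- function(char, step = 0.1) {
  stopifnot(inherits(char, "cord_characteristic"))
  grid <- seq(20, 80, by = step)
  t <- tension(char, grid)
  d <- diff(t)
  if (all(d <= 0)) {
    warning("tension is non-increasing throughout the 20-80% band; ",
            "degenerate characteristic", call. = FALSE)
    return(c(lo = 20, hi = 20))
  }
  bad <- which(d <= 0)
  hi <- if (length(bad) == 0L) 80 else grid[min(bad)]
  c(lo = 20, hi = hi)
}

#' @export
print.cord_characteristic <- function(x, ...) {
  cat(sprintf("<cord_characteristic> %s cord (rest %.4f m)\n",
              x$spec$kind, x$spec$rest_length_m))
  for (k in 1:3) {
    cat(sprintf("  term %d: %8.3f N * sin(%.6f x %+.6f)\n",
                k, x$amplitudes[k], x$frequencies[k], x$phases[k]))
  }
  if (!is.na(x$r_squared)) cat(sprintf("  R-squared: %.6f\n", x$r_squared))
  invisible(x)
}

#' Write / read a cord characteristic as JSON
#'
#' The JSON layout is `{kind, rest_length_m, terms:[{a_N, b_per_pct,
#' c_rad}], r_squared}` with full double precision, so a write/read cycle
#' reproduces the characteristic bit-exactly.
#'
#' @param char A [cord_characteristic()].
#' @param path File path.
#' @return `write_characteristic()` returns `path` invisibly;
#'   `read_characteristic()` returns a [cord_characteristic()].
#' @export
write_characteristic <- function(char, path) {
  stopifnot(inherits(char, "cord_characteristic"))
  obj <- list(
    kind = char$spec$kind,
    rest_length_m = char$spec$rest_length_m,
    terms = lapply(1:3, function(k) list(
      a_N = char$amplitudes[k],
      b_per_pct = char$frequencies[k],
      c_rad = char$phases[k]
    )),
    r_squared = if (is.na(char$r_squared)) NULL else char$r_squared
  )
  # 17 significant digits: doubles survive the write/read cycle bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_characteristic
#' @export
read_characteristic <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("kind", "rest_length_m", "terms")
  if (!all(need %in% names(obj))) {
    stop("not a cord characteristic JSON: missing ",
         paste(setdiff(need, names(obj)), collapse = ", "), call. = FALSE)
  }
  spec <- cord_spec(obj$kind, obj$rest_length_m)
  a <- vapply(obj$terms, function(t) t$a_N, numeric(1))
  b <- vapply(obj$terms, function(t) t$b_per_pct, numeric(1))
  c_ <- vapply(obj$terms, function(t) t$c_rad, numeric(1))
  r2 <- if (is.null(obj$r_squared)) NA_real_ else obj$r_squared
  cord_characteristic(spec, a, b, c_, r_squared = r2)
}
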