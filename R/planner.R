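# Inverse problem: find the cord configuration that yields a prescribed
# unweighting (or loading) fraction of body weight.

# unweighting produced by cords at a shared elongation
.forward_elongation <- function(subject, cords, angles_deg, elong_pct,
                                g = spider_gravity) {
  fz <- 0
  for (i in seq_along(cords)) {
    fz <- fz + tension(cords[[i]], elong_pct) * sin(angles_deg[i] * pi / 180)
  }
  fz / (subject$mass_kg * g)
}

# unweighting produced by all anchors raised to height z, each cord keeping
# its fixed horizontal radius and azimuth
.forward_anchor_height <- function(subject, cords, radii_m, z,
                                   g = spider_gravity) {
  h <- subject$cog_height_m
  fz <- 0
  for (i in seq_along(cords)) {
    len <- sqrt(radii_m[i]^2 + (z - h)^2)
    e <- elongation_pct(cords[[i]]$spec, len)
    fz <- fz + tension(cords[[i]], e) * (z - h) / len
  }
  fz / (subject$mass_kg * g)
}

.check_monotone <- function(f, lo, hi, n = 41) {
  xs <- seq(lo, hi, length.out = n)
  v <- vapply(xs, f, numeric(1))
  d <- diff(v)
  if (all(d >= 0) || all(d <= 0)) return(invisible(TRUE))
  stop("forward map is not monotone on the solve bracket; ",
       "cannot guarantee a unique configuration", call. = FALSE)
}

#' Solve for the configuration that achieves a target unweighting
#'
#' Inverse of the forward statics: given a subject, a cord set with fixed
#' COG-level angles (and azimuths), find the single free variable — a
#' shared elongation, or a shared anchor height — whose forward
#' simulation reproduces `target_unweighting`. Negative targets prescribe
#' net loading. The forward map is checked for monotonicity on the solve
#' bracket (so the solution is unique) and the root is found by Brent's
#' method; the returned configuration reproduces the target to within
#' `1e-6` of body weight.
#'
#' With `free = "elongation"` the bracket is 0 to the upper end of the
#' cords' common working range (the strictly-increasing part of the
#' desirable 20--80% band). With `free = "anchor_height"` each cord keeps
#' its current horizontal radius and azimuth while all anchors move to a
#' common height; the bracket keeps every cord within its working range.
#'
#' @param subject A [subject()].
#' @param cords List of [cord_characteristic()] objects.
#' @param angles_deg COG-level angle per cord, degrees (used when solving
#'   for elongation).
#' @param radii_m Horizontal anchor radius per cord, metres (used when
#'   solving for anchor height).
#' @param target_unweighting Target fraction of body weight in \[-1, 1\].
#' @param free `"elongation"` or `"anchor_height"`.
#' @param tol Root tolerance on the free variable.
#' @param g Gravitational acceleration, m/s^2.
#' @return List with the solved free variable (`elongation_pct` or
#'   `anchor_height_m`), the achieved `unweighting_fraction`, and the
#'   `achievable` interval of the forward map over the bracket.
#' @examples
#' ch <- reference_characteristic("reference_adult_thick")
#' sol <- solve_configuration(subject(75, 1.75), rep(list(ch), 4),
#'                            angles_deg = rep(45, 4),
#'                            target_unweighting = 0.15)
#' sol$elongation_pct
#' @export
solve_configuration <- function(subject, cords, angles_deg = NULL,
                                radii_m = NULL, target_unweighting,
                                free = c("elongation", "anchor_height"),
                                tol = 1e-9, g = spider_gravity) {
  free <- match.arg(free)
  stopifnot(inherits(subject, "spider_subject"), is.list(cords),
            length(cords) >= 1L,
            all(vapply(cords, inherits, logical(1), "cord_characteristic")))
  if (!is.numeric(target_unweighting) || length(target_unweighting) != 1L ||
      abs(target_unweighting) > 1) {
    stop("`target_unweighting` must be a single value in [-1, 1]",
         call. = FALSE)
  }

  if (free == "elongation") {
    if (is.null(angles_deg) || length(angles_deg) != length(cords)) {
      stop("`angles_deg` must give one COG-level angle per cord",
           call. = FALSE)
    }
    if (target_unweighting == 0) {
      # slack cords transmit no force regardless of model residual at x = 0
      return(list(unweighting_fraction = 0, achievable = NULL,
                  free = free, elongation_pct = 0))
    }
    hi <- min(vapply(cords, function(ch) working_range(ch)[2], numeric(1)))
    fwd <- function(e) .forward_elongation(subject, cords, angles_deg, e, g)
    lo <- 0
  } else {
    if (is.null(radii_m) || length(radii_m) != length(cords) ||
        any(radii_m <= 0)) {
      stop("`radii_m` must give one positive horizontal radius per cord",
           call. = FALSE)
    }
    h <- subject$cog_height_m
    # highest anchor keeping every cord at or below its working-range top
    z_top <- Inf
    for (i in seq_along(cords)) {
      e_hi <- working_range(cords[[i]])[2]
      len_hi <- cords[[i]]$spec$rest_length_m * (1 + e_hi / 100)
      if (len_hi > radii_m[i]) {
        z_top <- min(z_top, h + sqrt(len_hi^2 - radii_m[i]^2))
      }
    }
    if (!is.finite(z_top)) {
      stop("infeasible geometry: anchors cannot stretch any cord within ",
           "its working range", call. = FALSE)
    }
    fwd <- function(z) .forward_anchor_height(subject, cords, radii_m, z, g)
    lo <- h
    hi <- z_top
  }

  f_lo <- fwd(lo)
  f_hi <- fwd(hi)
  achievable <- sort(c(f_lo, f_hi))
  if (target_unweighting < achievable[1] - 1e-12 ||
      target_unweighting > achievable[2] + 1e-12) {
    stop(sprintf(
      "infeasible target: %.4f is outside the achievable unweighting interval [%.4f, %.4f]",
      target_unweighting, achievable[1], achievable[2]), call. = FALSE)
  }
  .check_monotone(fwd, lo, hi)

  obj <- function(v) fwd(v) - target_unweighting
  root <- if (abs(obj(lo)) <= 1e-15) lo
          else if (abs(obj(hi)) <= 1e-15) hi
          else stats::uniroot(obj, c(lo, hi), tol = tol,
                              f.lower = f_lo - target_unweighting,
                              f.upper = f_hi - target_unweighting)$root
  achieved <- fwd(root)
  if (abs(achieved - target_unweighting) > 1e-6) {
    stop("root refinement failed to reach the target within 1e-6",
         call. = FALSE)
  }
  out <- list(unweighting_fraction = achieved, achievable = achievable,
              free = free)
  if (free == "elongation") out$elongation_pct <- root
  else out$anchor_height_m <- root
  out
}
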