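# Anatomical frame, subject anthropometrics, and cord geometry.
#
# Frame convention (right-handed): Z vertical, up positive; X anterior (the
# subject faces +X, towards the frontal YZ plane); Y mediolateral, subject's
# left positive. Origin on the floor at the midpoint between the feet. The
# transverse plane is the horizontal plane through the COG; the sagittal
# plane is XZ.

.G <- 9.81  # m/s^2

#' Subject anthropometrics
#'
#' Mass, standing height and centre-of-gravity (COG) height above the
#' ground. The COG height is the single anthropometric input the model
#' needs: the belt routes every cord force through the COG level. The
#' device is rated to 110 kg (hard limit); its practical utility range for
#' adults is 70--80 kg, outside which an advisory message is emitted.
#'
#' @param mass_kg Body mass in kg; must be positive and at most 110.
#' @param height_m Standing height in metres.
#' @param cog_height_m COG height above ground in metres; when `NULL` it is
#'   estimated from height via [estimate_cog_height()].
#' @param age_class `"adult"` or `"child"`; selects the COG-height estimate
#'   fraction and whether the utility-range advisory applies.
#' @return An object of class `spider_subject`.
#' @examples
#' subject(75, 1.75)
#' subject(12, 0.88, age_class = "child")
#' @export
subject <- function(mass_kg, height_m, cog_height_m = NULL,
                    age_class = c("adult", "child")) {
  age_class <- match.arg(age_class)
  stopifnot(is.numeric(mass_kg), length(mass_kg) == 1L,
            is.numeric(height_m), length(height_m) == 1L)
  if (!is.finite(mass_kg) || mass_kg <= 0) {
    stop("`mass_kg` must be positive", call. = FALSE)
  }
  if (mass_kg > 110) {
    stop("mass ", mass_kg, " kg exceeds the 110 kg device limit",
         call. = FALSE)
  }
  if (age_class == "adult" && (mass_kg < 70 || mass_kg > 80)) {
    message(sprintf(
      "note: mass %.1f kg is outside the 70-80 kg adult utility range",
      mass_kg))
  }
  if (!is.finite(height_m) || height_m <= 0) {
    stop("`height_m` must be positive", call. = FALSE)
  }
  if (is.null(cog_height_m)) {
    cog_height_m <- estimate_cog_height(height_m, age_class)
  }
  if (!is.finite(cog_height_m) || cog_height_m <= 0 ||
      cog_height_m >= height_m) {
    stop("`cog_height_m` must satisfy 0 < cog_height_m < height_m",
         call. = FALSE)
  }
  structure(list(mass_kg = mass_kg, height_m = height_m,
                 cog_height_m = cog_height_m, age_class = age_class),
            class = "spider_subject")
}

#' @export
print.spider_subject <- function(x, ...) {
  cat(sprintf("<subject> %.1f kg, %.2f m tall, COG at %.3f m (%s)\n",
              x$mass_kg, x$height_m, x$cog_height_m, x$age_class))
  invisible(x)
}

#' Estimate COG height from standing height
#'
#' Convenience default for when the COG height has not been measured
#' directly (direct measurement is preferred). Uses the standard
#' anthropometric fractions 0.56 of stature for adults and 0.58 for young
#' children (children carry proportionally more mass cranially).
#'
#' @param height_m Standing height in metres.
#' @param age_class `"adult"` or `"child"`.
#' @return Estimated COG height in metres.
#' @examples
#' estimate_cog_height(1.75, "adult") # 0.98
#' @export
estimate_cog_height <- function(height_m, age_class = c("adult", "child")) {
  age_class <- match.arg(age_class)
  if (!is.numeric(height_m) || length(height_m) != 1L ||
      !is.finite(height_m) || height_m <= 0) {
    stop("`height_m` must be a positive number", call. = FALSE)
  }
  frac <- if (age_class == "adult") 0.56 else 0.58
  frac * height_m
}

#' Describe an installed cord by its endpoints
#'
#' A cord runs from a cage `anchor` point to a `belt` point on the carrying
#' belt. The belt is modelled as a single point per cord at the subject's
#' COG height, so the belt point's Z coordinate must equal
#' `subject$cog_height_m`.
#'
#' @param cord A [cord_characteristic()].
#' @param anchor Numeric length-3 point (metres, cage frame).
#' @param belt Numeric length-3 point on the belt at COG height.
#' @return An object of class `cord_attachment`.
#' @export
cord_attachment <- function(cord, anchor, belt) {
  stopifnot(inherits(cord, "cord_characteristic"),
            is.numeric(anchor), length(anchor) == 3L,
            is.numeric(belt), length(belt) == 3L,
            all(is.finite(anchor)), all(is.finite(belt)))
  structure(list(cord = cord, anchor = as.numeric(anchor),
                 belt = as.numeric(belt)),
            class = "cord_attachment")
}

#' Resolve the geometric and force state of one installed cord
#'
#' From an attachment, computes the belt-to-anchor unit direction, the
#' stretched length, the elongation percentage, the cord--COG-level angle
#' (the angle between the cord and the transverse plane, positive when the
#' anchor is above it, i.e. `asin` of the direction's Z component), and
#' the tension from the cord's characteristic.
#'
#' @param attachment A [cord_attachment()].
#' @return An object of class `cord_state` with fields `direction`,
#'   `stretched_length_m`, `elongation_pct`, `cog_level_angle_deg`,
#'   `tension_N`.
#' @export
cord_state <- function(attachment) {
  stopifnot(inherits(attachment, "cord_attachment"))
  v <- attachment$anchor - attachment$belt
  len <- sqrt(sum(v^2))
  if (len == 0) {
    stop("degenerate geometry: anchor coincides with belt point",
         call. = FALSE)
  }
  dir <- v / len
  elong <- elongation_pct(attachment$cord$spec, len)
  angle <- asin(max(-1, min(1, dir[3]))) * 180 / pi
  t <- tension(attachment$cord, elong)
  structure(list(
    direction = dir,
    stretched_length_m = len,
    elongation_pct = elong,
    cog_level_angle_deg = angle,
    tension_N = t,
    attachment = attachment
  ), class = "cord_state")
}

#' @export
print.cord_state <- function(x, ...) {
  cat(sprintf(
    "<cord_state> %.2f N at %.2f%% elongation, COG-level angle %+.1f deg\n",
    x$tension_N, x$elongation_pct, x$cog_level_angle_deg))
  invisible(x)
}

#' Does a cord unload or load the patient?
#'
#' A cord anchored above the waist belt (positive COG-level angle) pulls
#' upward and unloads the patient; anchored below, it loads; exactly at
#' belt level it is neutral.
#'
#' @param state A [cord_state()].
#' @return `"unload"`, `"load"` or `"neutral"`.
#' @export
loading_mode <- function(state) {
  stopifnot(inherits(state, "cord_state"))
  if (state$cog_level_angle_deg > 0) "unload"
  else if (state$cog_level_angle_deg < 0) "load"
  else "neutral"
}

#' Reconstruct a cord attachment from angle-and-elongation form
#'
#' Device setups are most naturally specified per cord by the COG-level
#' angle, the elongation, and an azimuth in the transverse plane (measured
#' from +X, anterior, toward +Y, the subject's left). This places the belt
#' point at `(0, 0, cog_height)` and the anchor at stretched-length
#' distance along the given direction, so that [cord_state()] round-trips
#' to the same angle and elongation.
#'
#' @param subject A [subject()].
#' @param cord A [cord_characteristic()].
#' @param cog_level_angle_deg Cord--COG-level angle, strictly between -90
#'   and 90 degrees (a vertical cord has no defined azimuth).
#' @param azimuth_deg Azimuth in the transverse plane, degrees.
#' @param elongation_pct Elongation in percent of rest length; give either
#'   this or `elongation_mm`.
#' @param elongation_mm Absolute stretch beyond rest length in millimetres,
#'   converted to percent using the cord's rest length.
#' @return A [cord_attachment()].
#' @examples
#' ch <- reference_characteristic("reference_adult_thick")
#' att <- attachment_from_polar(subject(75, 1.75), ch, 45, 45,
#'                              elongation_mm = 250)
#' cord_state(att)
#' @export
attachment_from_polar <- function(subject, cord, cog_level_angle_deg,
                                  azimuth_deg, elongation_pct = NULL,
                                  elongation_mm = NULL) {
  stopifnot(inherits(subject, "spider_subject"),
            inherits(cord, "cord_characteristic"))
  if (abs(cog_level_angle_deg) >= 90) {
    stop("ambiguous azimuth: a cord at +/-90 degrees is vertical; ",
         "COG-level angle must lie strictly within (-90, 90)",
         call. = FALSE)
  }
  if (is.null(elongation_pct) == is.null(elongation_mm)) {
    stop("give exactly one of `elongation_pct` or `elongation_mm`",
         call. = FALSE)
  }
  if (is.null(elongation_pct)) {
    elongation_pct <- 100 * (elongation_mm / 1000) / cord$spec$rest_length_m
  }
  if (elongation_pct < 0) {
    stop("`elongation_pct` must be non-negative", call. = FALSE)
  }
  el <- cog_level_angle_deg * pi / 180
  az <- azimuth_deg * pi / 180
  len <- cord$spec$rest_length_m * (1 + elongation_pct / 100)
  belt <- c(0, 0, subject$cog_height_m)
  dir <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  cord_attachment(cord, anchor = belt + len * dir, belt = belt)
}
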