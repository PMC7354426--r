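# Rigid-body statics: reduction of cord tensions and gravity to a COG
# resultant and two foot-ground-contact (FGC) reactions.

#' Standard gravity used throughout the package (m/s^2)
#' @export
spider_gravity <- 9.81

#' Resultant cord force at the COG and unweighting fraction
#'
#' Sums each cord's tension along its belt-to-anchor direction. The
#' unweighting fraction is the vertical (Z) component of that resultant
#' divided by body weight `m g`: positive values unweight (relieve) the
#' body, negative values add load.
#'
#' @param subject A [subject()].
#' @param states List of [cord_state()] objects (at least one).
#' @param g Gravitational acceleration, m/s^2.
#' @return List with `cog_resultant` (numeric XYZ, newtons) and
#'   `unweighting_fraction`.
#' @export
resolve_cog <- function(subject, states, g = spider_gravity) {
  stopifnot(inherits(subject, "spider_subject"))
  if (!is.list(states) || length(states) == 0L ||
      !all(vapply(states, inherits, logical(1), "cord_state"))) {
    stop("`states` must be a non-empty list of cord_state objects",
         call. = FALSE)
  }
  f <- c(0, 0, 0)
  for (s in states) f <- f + s$tension_N * s$direction
  list(cog_resultant = f,
       unweighting_fraction = f[3] / (subject$mass_kg * g))
}

#' Two-point stance
#'
#' Foot-ground contact points on the floor (Z = 0). The default symmetric
#' stance places the feet 0.30 m apart about the origin, left foot on the
#' +Y side.
#'
#' @param left,right Numeric length-3 FGC positions in metres, or `NULL`
#'   for a single-foot stance.
#' @export
stance <- function(left = c(0, 0.15, 0), right = c(0, -0.15, 0)) {
  if (is.null(left) && is.null(right)) {
    stop("at least one foot must be in contact", call. = FALSE)
  }
  chk <- function(p, side) {
    if (is.null(p)) return(NULL)
    stopifnot(is.numeric(p), length(p) == 3L, all(is.finite(p)))
    if (abs(p[3]) > 1e-9) {
      stop(side, " foot must be on the floor (Z = 0)", call. = FALSE)
    }
    as.numeric(p)
  }
  structure(list(left = chk(left, "left"), right = chk(right, "right")),
            class = "spider_stance")
}

#' Partition the ground reaction between the two feet
#'
#' The whole body is in static equilibrium under gravity (acting through
#' the COG, on the vertical line through the origin), the cord resultant
#' at the COG, and the two FGC reactions. The vertical reactions are the
#' unique solution of vertical force balance plus lateral (frontal-plane)
#' moment balance about the COG's vertical projection; the fore-aft moment
#' residual is absorbed by centre-of-pressure shift within the foot and is
#' not modelled. The net horizontal cord force is reacted at the feet as
#' friction, split in proportion to each foot's vertical load, which
#' preserves componentwise equilibrium and mirror symmetry.
#'
#' If the cords carry the full body weight or more, both reactions are
#' zero and `lift_off` is flagged (contact is unilateral: the ground
#' cannot pull).
#'
#' @param subject A [subject()].
#' @param cog_resultant Numeric XYZ cord resultant at the COG, newtons.
#' @param stance_pts A [stance()].
#' @param g Gravitational acceleration, m/s^2.
#' @return List with `left`, `right` (numeric XYZ reactions, newtons;
#'   zero vector for a foot not in contact) and `lift_off` (logical).
#' @export
foot_reactions <- function(subject, cog_resultant, stance_pts = stance(),
                           g = spider_gravity) {
  stopifnot(inherits(subject, "spider_subject"),
            inherits(stance_pts, "spider_stance"),
            is.numeric(cog_resultant), length(cog_resultant) == 3L)
  w <- subject$mass_kg * g
  v_net <- w - cog_resultant[3]          # total vertical support needed
  if (v_net <= 0) {
    return(list(left = c(0, 0, 0), right = c(0, 0, 0), lift_off = TRUE))
  }
  h <- subject$cog_height_m
  fx <- cog_resultant[1]
  fy <- cog_resultant[2]

  if (is.null(stance_pts$left) || is.null(stance_pts$right)) {
    # single-foot stance: that foot carries everything
    r <- c(-fx, -fy, v_net)
    if (is.null(stance_pts$left)) {
      return(list(left = c(0, 0, 0), right = r, lift_off = FALSE))
    }
    return(list(left = r, right = c(0, 0, 0), lift_off = FALSE))
  }

  yl <- stance_pts$left[2]
  yr <- stance_pts$right[2]
  if (yl == yr) {
    vl <- v_net / 2
    vr <- v_net / 2
  } else {
    # lateral moment balance about the COG vertical projection:
    #   yl*vl + yr*vr = h*fy ; vl + vr = v_net
    # closed forms keep sagittal mirror symmetry bit-exact
    vl <- (h * fy - yr * v_net) / (yl - yr)
    vr <- (yl * v_net - h * fy) / (yl - yr)
  }
  list(
    left = c(-fx * vl / v_net, -fy * vl / v_net, vl),
    right = c(-fx * vr / v_net, -fy * vr / v_net, vr),
    lift_off = FALSE
  )
}

#' Classify heel and toe loading from the cord-imposed foot force
#'
#' Operates on the cord-imposed force at a foot (see [summarize_loads()]):
#' a positive vertical (Z) component unweights the heel, a negative one
#' loads it; a positive mediolateral (Y) component moves load toward the
#' toe mound, a negative one moves it away.
#'
#' @param force Numeric XYZ cord-imposed force at the FGC, newtons.
#' @return List with `heel_state` (`"unweighted"`, `"loaded"`,
#'   `"neutral"`) and `toe_state` (`"load_toward"`, `"load_away"`,
#'   `"neutral"`).
#' @export
classify_foot_load <- function(force) {
  stopifnot(is.numeric(force), length(force) == 3L, all(is.finite(force)))
  heel <- if (force[3] > 0) "unweighted"
          else if (force[3] < 0) "loaded" else "neutral"
  toe <- if (force[2] > 0) "load_toward"
         else if (force[2] < 0) "load_away" else "neutral"
  list(heel_state = heel, toe_state = toe)
}

#' Scale all cord tensions by a common factor
#'
#' Therapists adjust treatment intensity by increasing or decreasing cord
#' tension by 10--20%; this models that adjustment. Geometry is unchanged;
#' the downstream unweighting fraction scales linearly by the same factor.
#' Factors outside \[0.8, 1.2\] are applied with a warning.
#'
#' @param states List of [cord_state()] objects.
#' @param factor Non-negative scale factor.
#' @return List of [cord_state()] objects with scaled tensions.
#' @export
perturb_tension <- function(states, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, is.finite(factor))
  if (factor < 0) {
    stop("`factor` must be non-negative", call. = FALSE)
  }
  if (factor < 0.8 || factor > 1.2) {
    warning("tension factor ", factor,
            " is outside the usual 0.8-1.2 adjustment range; applied anyway",
            call. = FALSE)
  }
  lapply(states, function(s) {
    s$tension_N <- s$tension_N * factor
    s
  })
}

#' Full load summary for a configured scenario
#'
#' Runs the whole static reduction: COG resultant and unweighting fraction
#' from [resolve_cog()], foot reactions from [foot_reactions()], and the
#' cord-imposed force at each foot with heel/toe classification. The
#' cord-imposed force at a foot is the baseline (no-cord) reaction minus
#' the actual reaction; the two cord-imposed forces sum exactly to the COG
#' cord resultant.
#'
#' @inheritParams foot_reactions
#' @param states List of [cord_state()] objects.
#' @return An object of class `load_summary`.
#' @export
summarize_loads <- function(subject, states, stance_pts = stance(),
                            g = spider_gravity) {
  res <- resolve_cog(subject, states, g = g)
  reac <- foot_reactions(subject, res$cog_resultant, stance_pts, g = g)
  base <- foot_reactions(subject, c(0, 0, 0), stance_pts, g = g)
  imposed_left <- base$left - reac$left
  imposed_right <- base$right - reac$right
  structure(list(
    subject = subject,
    states = states,
    stance = stance_pts,
    cog_resultant = res$cog_resultant,
    unweighting_fraction = res$unweighting_fraction,
    left_foot = reac$left,
    right_foot = reac$right,
    lift_off = reac$lift_off,
    cord_imposed = list(left = imposed_left, right = imposed_right),
    left_classification = classify_foot_load(imposed_left),
    right_classification = classify_foot_load(imposed_right)
  ), class = "load_summary")
}

#' @export
print.load_summary <- function(x, ...) {
  cat("<load_summary>\n")
  cat(sprintf("  subject: %.1f kg (weight %.1f N)\n",
              x$subject$mass_kg, x$subject$mass_kg * spider_gravity))
  cat(sprintf("  COG cord resultant [N]: X %+.2f  Y %+.2f  Z %+.2f\n",
              x$cog_resultant[1], x$cog_resultant[2], x$cog_resultant[3]))
  cat(sprintf("  unweighting: %.2f%% of body weight%s\n",
              100 * x$unweighting_fraction,
              if (x$unweighting_fraction < 0) " (net loading)" else ""))
  if (x$lift_off) {
    cat("  LIFT-OFF: cords carry the full body weight; feet unloaded\n")
    return(invisible(x))
  }
  fmt <- function(side, r, cl) {
    cat(sprintf("  %s foot reaction [N]: X %+.2f  Y %+.2f  Z %+.2f  (heel %s, toe %s)\n",
                side, r[1], r[2], r[3], cl$heel_state, cl$toe_state))
  }
  fmt("left ", x$left_foot, x$left_classification)
  fmt("right", x$right_foot, x$right_classification)
  invisible(x)
}
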