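# Scenario configuration files (YAML/JSON), simulation driver, and force
# table output.
#
# Schema (keys carry their units):
#   subject: mass_kg, height_m, cog_height_m (optional), age_class (optional)
#   cords: list of
#     kind, rest_length_m (optional), characteristic (fixture name or JSON
#     path), cog_level_angle_deg + azimuth_deg + elongation_mm|elongation_pct
#     (polar form)  OR  anchor_m: [x, y, z] (Cartesian form)
#   stance: left_foot_m, right_foot_m ([x, y, z] on the floor, or null)
# Unknown keys anywhere are rejected by name.

.SCHEMA <- list(
  top = c("subject", "cords", "stance"),
  subject = c("mass_kg", "height_m", "cog_height_m", "age_class"),
  cord = c("kind", "rest_length_m", "characteristic", "cog_level_angle_deg",
           "azimuth_deg", "elongation_mm", "elongation_pct", "anchor_m"),
  stance = c("left_foot_m", "right_foot_m")
)

.check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0L) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

#' Read and write scenario configuration files
#'
#' A scenario bundles a subject, a cord set (in polar
#' angle/azimuth/elongation form or Cartesian anchor form) and a stance.
#' YAML and JSON are supported, chosen by file extension. Unknown keys are
#' rejected with a named error; all keys carry explicit units (`_kg`,
#' `_m`, `_mm`, `_deg`). A write/read cycle is the identity on all fields.
#'
#' @param path File path (`.yaml`, `.yml` or `.json`).
#' @param scenario A scenario list as returned by `read_scenario()`.
#' @return `read_scenario()` returns the validated scenario list (class
#'   `spider_scenario`); `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    # simplify scalars/vectors like the YAML reader, but keep the cord
    # list as a list of blocks, not a data frame
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_scenario(raw)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  sc <- validate_scenario(scenario)
  sc <- unclass(sc)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(sc, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(sc, path)
  }
  invisible(path)
}

#' @rdname read_scenario
#' @param scenario A raw scenario list to validate against the schema.
#' @export
validate_scenario <- function(scenario) {
  sc <- scenario
  class(sc) <- NULL
  .check_keys(sc, .SCHEMA$top, "scenario")
  if (is.null(sc$subject) || is.null(sc$cords)) {
    stop("scenario must have `subject` and `cords` blocks", call. = FALSE)
  }
  .check_keys(sc$subject, .SCHEMA$subject, "subject")
  if (is.null(sc$subject$mass_kg) || is.null(sc$subject$height_m)) {
    stop("subject block needs `mass_kg` and `height_m`", call. = FALSE)
  }
  for (i in seq_along(sc$cords)) {
    cd <- sc$cords[[i]]
    .check_keys(cd, .SCHEMA$cord, sprintf("cords[%d]", i))
    polar <- !is.null(cd$cog_level_angle_deg)
    cart <- !is.null(cd$anchor_m)
    if (polar == cart) {
      stop(sprintf(
        "cords[%d]: give either polar form (cog_level_angle_deg, azimuth_deg, elongation) or Cartesian `anchor_m`",
        i), call. = FALSE)
    }
    if (polar && is.null(cd$elongation_mm) && is.null(cd$elongation_pct)) {
      stop(sprintf("cords[%d]: polar form needs `elongation_mm` or `elongation_pct`",
                   i), call. = FALSE)
    }
    if (is.null(cd$characteristic) && is.null(cd$kind)) {
      stop(sprintf("cords[%d]: needs `characteristic` or `kind`", i),
           call. = FALSE)
    }
  }
  if (!is.null(sc$stance)) .check_keys(sc$stance, .SCHEMA$stance, "stance")
  structure(sc, class = "spider_scenario")
}

# resolve a cord block to a cord_characteristic
.resolve_characteristic <- function(cd) {
  if (!is.null(cd$characteristic)) {
    nm <- cd$characteristic
    if (nm %in% names(.fixture_params)) {
      ch <- reference_characteristic(nm)
    } else if (file.exists(nm)) {
      ch <- read_characteristic(nm)
    } else {
      stop("unknown characteristic: ", nm,
           " (not a packaged fixture name or an existing JSON file)",
           call. = FALSE)
    }
    if (!is.null(cd$rest_length_m)) {
      ch$spec <- cord_spec(ch$spec$kind, cd$rest_length_m)
    }
    return(ch)
  }
  stop("cords without a `characteristic` cannot be simulated; ",
       "fit one with fit_sum_of_sines() or use a packaged fixture",
       call. = FALSE)
}

#' Simulate a scenario
#'
#' Builds the cord states from a scenario configuration (resolving
#' characteristics from packaged fixture names or JSON files), runs the
#' full static reduction, and returns the [summarize_loads()] result.
#'
#' @param scenario A scenario list or a path to a scenario file.
#' @param g Gravitational acceleration, m/s^2.
#' @return A `load_summary`.
#' @examples
#' path <- system.file("extdata", "scenario_adult_symmetric.yaml",
#'                     package = "spiderstat")
#' simulate_scenario(path)
#' @export
simulate_scenario <- function(scenario, g = spider_gravity) {
  sc <- if (is.character(scenario)) read_scenario(scenario)
        else validate_scenario(scenario)
  sb <- sc$subject
  subj <- suppressMessages(subject(
    mass_kg = sb$mass_kg, height_m = sb$height_m,
    cog_height_m = sb$cog_height_m,
    age_class = if (is.null(sb$age_class)) "adult" else sb$age_class))
  states <- lapply(sc$cords, function(cd) {
    ch <- .resolve_characteristic(cd)
    att <- if (!is.null(cd$anchor_m)) {
      cord_attachment(ch, anchor = unlist(cd$anchor_m),
                      belt = c(0, 0, subj$cog_height_m))
    } else {
      attachment_from_polar(subj, ch,
                            cog_level_angle_deg = cd$cog_level_angle_deg,
                            azimuth_deg = cd$azimuth_deg,
                            elongation_pct = cd$elongation_pct,
                            elongation_mm = cd$elongation_mm)
    }
    cord_state(att)
  })
  st <- if (is.null(sc$stance)) {
    stance()
  } else {
    stance(left = if (is.null(sc$stance$left_foot_m)) NULL
                  else unlist(sc$stance$left_foot_m),
           right = if (is.null(sc$stance$right_foot_m)) NULL
                   else unlist(sc$stance$right_foot_m))
  }
  summarize_loads(subj, states, st, g = g)
}

#' Write a force table for a load summary
#'
#' CSV (or JSON) table with one row per cord (tension, direction, force
#' components, COG-level angle, loading mode) followed by rows for the
#' COG resultant, unweighting percentage, per-foot reactions and
#' cord-imposed forces with heel/toe classification. Column names are
#' stable: `item, tension_N, angle_deg, mode, fx_N, fy_N, fz_N, note`.
#'
#' @param summary A `load_summary` from [summarize_loads()] or
#'   [simulate_scenario()].
#' @param path Output path; format chosen by extension (`.csv` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_force_table <- function(summary, path) {
  stopifnot(inherits(summary, "load_summary"))
  rows <- list()
  for (i in seq_along(summary$states)) {
    s <- summary$states[[i]]
    f <- s$tension_N * s$direction
    rows[[length(rows) + 1L]] <- data.frame(
      item = sprintf("cord_%d", i), tension_N = s$tension_N,
      angle_deg = s$cog_level_angle_deg, mode = loading_mode(s),
      fx_N = f[1], fy_N = f[2], fz_N = f[3], note = "")
  }
  add <- function(item, f, mode = "", note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      item = item, tension_N = NA_real_, angle_deg = NA_real_, mode = mode,
      fx_N = f[1], fy_N = f[2], fz_N = f[3], note = note)
  }
  add("cog_resultant", summary$cog_resultant,
      note = sprintf("unweighting_pct=%.6f",
                     100 * summary$unweighting_fraction))
  add("left_foot_reaction", summary$left_foot,
      note = if (summary$lift_off) "lift_off" else "")
  add("right_foot_reaction", summary$right_foot,
      note = if (summary$lift_off) "lift_off" else "")
  add("left_foot_cord_imposed", summary$cord_imposed$left,
      mode = paste0("heel_", summary$left_classification$heel_state),
      note = paste0("toe_", summary$left_classification$toe_state))
  add("right_foot_cord_imposed", summary$cord_imposed$right,
      mode = paste0("heel_", summary$right_classification$heel_state),
      note = paste0("toe_", summary$right_classification$toe_state))
  tab <- do.call(rbind, rows)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA,
                         na = "null")
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
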