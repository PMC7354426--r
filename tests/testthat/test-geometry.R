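# Frame geometry: subject anthropometrics, cord state resolution,
# load/unload classification, polar round-trips.

test_that("subject validates mass and COG height", {
  expect_error(subject(115, 1.8), "110 kg")
  expect_error(subject(-5, 1.8), "positive")
  expect_message(subject(50, 1.7), "utility range")
  expect_silent(s <- subject(75, 1.75))
  expect_equal(s$cog_height_m, 0.56 * 1.75)
  # child class uses the child fraction and skips the adult advisory
  expect_silent(c <- subject(12, 0.88, age_class = "child"))
  expect_equal(c$cog_height_m, 0.58 * 0.88)
  expect_error(subject(75, 1.75, cog_height_m = 2), "cog_height_m")
})

test_that("COG height estimate uses the documented stature fractions", {
  expect_equal(estimate_cog_height(1.75, "adult"), 0.98)
  expect_equal(estimate_cog_height(0.88, "child"), 0.5104)
  expect_error(estimate_cog_height(0), "positive")
})

test_that("cord state resolves direction, length, elongation and angle", {
  ch <- monotone_char()
  belt <- c(0, 0, 1)
  # anchor directly above the belt: vertical cord, +90 degrees
  up <- cord_state(cord_attachment(ch, belt + c(0, 0, 0.7), belt))
  expect_equal(up$cog_level_angle_deg, 90)
  expect_equal(up$direction, c(0, 0, 1))
  # anchor at belt height: in-plane cord, 0 degrees
  side <- cord_state(cord_attachment(ch, belt + c(0, 1, 0), belt))
  expect_equal(side$cog_level_angle_deg, 0)
  # 3-4-5-style offset: |v| = sqrt(0.5), angle = asin(0.5/sqrt(0.5)) = 45
  off <- cord_state(cord_attachment(ch, belt + c(0.3, 0.4, 0.5), belt))
  expect_equal(off$stretched_length_m, sqrt(0.5), tolerance = 1e-12)
  expect_equal(off$cog_level_angle_deg, 45, tolerance = 1e-9)
  expect_equal(sqrt(sum(off$direction^2)), 1, tolerance = 1e-12)
  expect_equal(sin(off$cog_level_angle_deg * pi / 180), off$direction[3],
               tolerance = 1e-12)
  expect_error(cord_state(cord_attachment(ch, belt, belt)), "degenerate")
})

test_that("a cord anchored above the belt unloads, below loads", {
  ch <- monotone_char()
  belt <- c(0, 0, 1)
  mk <- function(dz) {
    cord_state(cord_attachment(ch, belt + c(0.5, 0, dz), belt))
  }
  expect_identical(loading_mode(mk(0.5)), "unload")
  expect_identical(loading_mode(mk(-0.3)), "load")
  expect_identical(loading_mode(mk(0)), "neutral")
})

test_that("polar attachment round-trips through cord_state", {
  subj <- subject(75, 1.75)
  ch <- monotone_char()
  att <- attachment_from_polar(subj, ch, cog_level_angle_deg = 45,
                               azimuth_deg = 135, elongation_mm = 250)
  st <- cord_state(att)
  expect_equal(st$cog_level_angle_deg, 45, tolerance = 1e-9)
  expect_equal(st$elongation_pct, 100 * 0.250 / ch$spec$rest_length_m,
               tolerance = 1e-9)
  # mm elongation on a thin cord
  thin <- monotone_char(kind = "thin")
  att2 <- attachment_from_polar(subj, thin, 10, 0, elongation_mm = 100)
  expect_equal(cord_state(att2)$elongation_pct, 100 * 0.100 / 0.6375,
               tolerance = 1e-9)
  expect_error(attachment_from_polar(subj, ch, 90, 0, elongation_pct = 10),
               "ambiguous azimuth")
  expect_error(attachment_from_polar(subj, ch, 45, 0), "exactly one")
})

test_that("polar round-trip holds over random configurations", {
  subj <- suppressMessages(subject(60, 1.7))
  ch <- monotone_char()
  set.seed(2024)
  for (i in 1:50) {
    ang <- runif(1, -89, 89)
    az <- runif(1, 0, 360)
    el <- runif(1, 0, 100)
    st <- cord_state(attachment_from_polar(subj, ch, ang, az,
                                           elongation_pct = el))
    expect_equal(st$cog_level_angle_deg, ang, tolerance = 1e-9)
    expect_equal(st$elongation_pct, el, tolerance = 1e-9)
    # angle sign always matches the anchor-belt height difference
    att <- st$attachment
    expect_identical(sign(st$cog_level_angle_deg),
                     sign(att$anchor[3] - att$belt[3]))
  }
})

test_that("cord state is invariant under rigid translation", {
  ch <- monotone_char()
  anchor <- c(0.8, -0.4, 1.6)
  belt <- c(0, 0, 0.98)
  shift <- c(0.3, -1.1, 0.25)
  a <- cord_state(cord_attachment(ch, anchor, belt))
  b <- cord_state(cord_attachment(ch, anchor + shift, belt + shift))
  expect_equal(a$direction, b$direction, tolerance = 1e-12)
  expect_equal(a$stretched_length_m, b$stretched_length_m, tolerance = 1e-12)
  expect_equal(a$tension_N, b$tension_N, tolerance = 1e-12)
})
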