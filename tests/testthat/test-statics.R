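# Static reduction: COG resultant, unweighting, foot partition,
# classification, perturbation, and the rigid-body invariants.

test_that("COG resultant is the tension-weighted sum of cord directions", {
  scn <- { set.seed(31); random_scenario() }
  res <- resolve_cog(scn$subject, scn$states)
  # independent naive loop
  f <- c(0, 0, 0)
  for (s in scn$states) f <- f + s$tension_N * s$direction
  expect_identical(res$cog_resultant, f)
  expect_identical(res$unweighting_fraction,
                   f[3] / (scn$subject$mass_kg * spider_gravity))
  expect_error(resolve_cog(scn$subject, list()), "non-empty")
})

test_that("zero tensions give a zero resultant and zero unweighting", {
  scn <- { set.seed(5); random_scenario() }
  slack <- suppressWarnings(perturb_tension(scn$states, 0))
  res <- resolve_cog(scn$subject, slack)
  expect_equal(res$cog_resultant, c(0, 0, 0))
  expect_equal(res$unweighting_fraction, 0)
})

test_that("a symmetric configuration splits the load equally", {
  subj <- subject(75, 1.75)
  ch <- reference_characteristic("reference_adult_thick")
  states <- lapply(c(45, 135, 225, 315), function(az) {
    cord_state(attachment_from_polar(subj, ch, 45, az, elongation_mm = 250))
  })
  res <- resolve_cog(subj, states)
  # an exactly symmetric resultant splits bit-identically
  sym <- foot_reactions(subj, c(0, 0, res$cog_resultant[3]), stance())
  expect_identical(sym$left[3], sym$right[3])
  # the simulated resultant carries ~1e-14 N of lateral summation residue
  reac <- foot_reactions(subj, res$cog_resultant, stance())
  expect_equal(reac$left[3], reac$right[3], tolerance = 1e-12)
  expect_equal(reac$left[3],
               (subj$mass_kg * spider_gravity - res$cog_resultant[3]) / 2,
               tolerance = 1e-12)
})

test_that("whole-body equilibrium closes on random two-foot scenarios", {
  set.seed(101)
  for (i in 1:200) {
    scn <- random_scenario()
    res <- resolve_cog(scn$subject, scn$states)
    reac <- foot_reactions(scn$subject, res$cog_resultant, scn$stance)
    if (reac$lift_off) next
    w <- c(0, 0, -scn$subject$mass_kg * spider_gravity)
    closure <- res$cog_resultant + w + reac$left + reac$right
    expect_lt(max(abs(closure)),
              1e-9 * scn$subject$mass_kg * spider_gravity)
  }
})

test_that("vertical split agrees with the independent moment-balance solve", {
  set.seed(202)
  for (i in 1:50) {
    scn <- random_scenario()
    res <- resolve_cog(scn$subject, scn$states)
    reac <- foot_reactions(scn$subject, res$cog_resultant, scn$stance)
    if (reac$lift_off) next
    v_net <- scn$subject$mass_kg * spider_gravity - res$cog_resultant[3]
    vo <- oracle_vertical_split(v_net, scn$stance$left[2],
                                scn$stance$right[2],
                                scn$subject$cog_height_m,
                                res$cog_resultant[2])
    expect_equal(reac$left[3], vo[1], tolerance = 1e-9)
    expect_equal(reac$right[3], vo[2], tolerance = 1e-9)
  }
})

test_that("a laterally offset resultant shifts load between the feet", {
  subj <- suppressMessages(subject(60, 1.7))
  # one cord pulling up and to the subject's left
  ch <- monotone_char(a = 200)
  st <- cord_state(attachment_from_polar(subj, ch, 50, 90,
                                         elongation_pct = 80))
  res <- resolve_cog(subj, list(st))
  reac <- foot_reactions(subj, res$cog_resultant, stance())
  expect_true(reac$left[3] != reac$right[3])
  expect_gt(reac$left[3] + reac$right[3], 0)
})

test_that("sagittal mirror swaps feet and negates Y exactly", {
  set.seed(303)
  for (i in 1:25) {
    scn <- random_scenario()
    mir <- mirror_scenario(scn)
    a <- summarize_loads(scn$subject, scn$states, scn$stance)
    b <- summarize_loads(mir$subject, mir$states, mir$stance)
    flip <- function(p) c(p[1], -p[2], p[3])
    expect_identical(b$cog_resultant, flip(a$cog_resultant))
    expect_identical(b$left_foot, flip(a$right_foot))
    expect_identical(b$right_foot, flip(a$left_foot))
  }
})

test_that("full suspension flags lift-off with zero reactions", {
  subj <- suppressMessages(subject(20, 1.2))
  ch <- monotone_char(a = 500)  # strong enough to exceed body weight
  states <- lapply(c(0, 180), function(az) {
    cord_state(attachment_from_polar(subj, ch, 80, az, elongation_pct = 95))
  })
  res <- resolve_cog(subj, states)
  expect_gt(res$unweighting_fraction, 1)
  reac <- foot_reactions(subj, res$cog_resultant, stance())
  expect_true(reac$lift_off)
  expect_equal(reac$left, c(0, 0, 0))
  expect_equal(reac$right, c(0, 0, 0))
})

test_that("single-foot stance routes the whole load to that foot", {
  scn <- { set.seed(9); random_scenario() }
  res <- resolve_cog(scn$subject, scn$states)
  reac <- foot_reactions(scn$subject, res$cog_resultant,
                         stance(left = NULL, right = c(0, -0.1, 0)))
  expect_equal(reac$left, c(0, 0, 0))
  w <- c(0, 0, -scn$subject$mass_kg * spider_gravity)
  expect_lt(max(abs(res$cog_resultant + w + reac$right)), 1e-9)
})

test_that("heel and toe classification follows the force signs", {
  expect_identical(classify_foot_load(c(0, 0, 12)),
                   list(heel_state = "unweighted", toe_state = "neutral"))
  expect_identical(classify_foot_load(c(1, -3, -5)),
                   list(heel_state = "loaded", toe_state = "load_away"))
  expect_identical(classify_foot_load(c(0, 0, 0)),
                   list(heel_state = "neutral", toe_state = "neutral"))
  expect_identical(classify_foot_load(c(0, 4, 0))$toe_state, "load_toward")
})

test_that("cord-imposed foot forces sum to the COG resultant", {
  set.seed(404)
  for (i in 1:20) {
    scn <- random_scenario()
    sm <- summarize_loads(scn$subject, scn$states, scn$stance)
    if (sm$lift_off) next
    expect_equal(sm$cord_imposed$left + sm$cord_imposed$right,
                 sm$cog_resultant, tolerance = 1e-9)
  }
})

test_that("tension perturbation is linear and leaves geometry alone", {
  scn <- { set.seed(7); random_scenario() }
  base <- resolve_cog(scn$subject, scn$states)
  expect_identical(perturb_tension(scn$states, 1)[[1]]$tension_N,
                   scn$states[[1]]$tension_N)
  for (f in c(0.8, 1.2)) {
    res <- resolve_cog(scn$subject, perturb_tension(scn$states, f))
    expect_equal(res$unweighting_fraction, f * base$unweighting_fraction,
                 tolerance = 1e-12)
    expect_identical(perturb_tension(scn$states, f)[[1]]$direction,
                     scn$states[[1]]$direction)
  }
  expect_warning(perturb_tension(scn$states, 1.5), "0.8-1.2")
  expect_error(perturb_tension(scn$states, -0.1), "non-negative")
})

test_that("unweighting is monotone in each cord's tension", {
  scn <- { set.seed(88); random_scenario() }
  # keep only unloading cords so scaling one up must not decrease lift
  ups <- Filter(function(s) s$cog_level_angle_deg > 0, scn$states)
  if (length(ups) >= 2) {
    base <- resolve_cog(scn$subject, ups)$unweighting_fraction
    for (k in seq_along(ups)) {
      bumped <- ups
      bumped[[k]]$tension_N <- bumped[[k]]$tension_N * 1.1
      expect_gte(resolve_cog(scn$subject, bumped)$unweighting_fraction, base)
    }
  }
})
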