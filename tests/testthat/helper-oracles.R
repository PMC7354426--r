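# Shared builders and independent oracles for the test suite.

# analytic monotone single-term characteristic: a sin(bx), increasing on
# [0, 100] when b <= pi/200
monotone_char <- function(a = 10, b = pi / 200, kind = "thick") {
  cord_characteristic(cord_spec(kind), c(a, 0, 0), c(b, 1, 1), c(0, 0, 0))
}

# three-term characteristic with known coefficients, positive on [0, 100]
known_char <- function(kind = "thick") {
  cord_characteristic(cord_spec(kind),
                      amplitudes = c(40, 25, 10),
                      frequencies = c(pi / 180, pi / 90, pi / 60),
                      phases = c(0.1, 0.4, -0.2))
}

raw_sos <- function(char, x) {
  char$amplitudes[1] * sin(char$frequencies[1] * x + char$phases[1]) +
    char$amplitudes[2] * sin(char$frequencies[2] * x + char$phases[2]) +
    char$amplitudes[3] * sin(char$frequencies[3] * x + char$phases[3])
}

# noiseless bench table sampled from a characteristic
bench_from_char <- function(char, grid = seq(0, 100, by = 5)) {
  as_bench_table(data.frame(elongation_pct = grid,
                            force_N = pmax(0, raw_sos(char, grid))))
}

# independent dense-grid scan for the strictly increasing sub-band of
# [20, 80] (the oracle for working_range)
scan_increasing_band <- function(char, step = 0.1) {
  grid <- seq(20, 80, by = step)
  t <- tension(char, grid)
  hi <- 80
  for (i in seq_len(length(grid) - 1L)) {
    if (t[i + 1L] <= t[i]) { hi <- grid[i]; break }  # last rising point
  }
  c(20, hi)
}

# independent 2-unknown moment-balance solve for vertical foot loads:
# solves [1 1; yl yr] [vl vr]' = [v_net, h*fy]' with base R
oracle_vertical_split <- function(v_net, yl, yr, h, fy) {
  A <- rbind(c(1, 1), c(yl, yr))
  as.numeric(solve(A, c(v_net, h * fy)))
}

# a random simulatable subject + cord states + stance (no lift-off)
random_scenario <- function() {
  subj <- suppressMessages(subject(
    mass_kg = runif(1, 20, 100),
    height_m = runif(1, 1.2, 1.9)))
  n <- sample(2:5, 1)
  states <- lapply(seq_len(n), function(i) {
    ch <- monotone_char(a = runif(1, 5, 30), b = runif(1, 0.3, 1) * pi / 200)
    att <- attachment_from_polar(
      subj, ch,
      cog_level_angle_deg = runif(1, -60, 80),
      azimuth_deg = runif(1, 0, 360),
      elongation_pct = runif(1, 10, 90))
    cord_state(att)
  })
  st <- stance(left = c(runif(1, -0.1, 0.1), runif(1, 0.05, 0.25), 0),
               right = c(runif(1, -0.1, 0.1), runif(1, -0.25, -0.05), 0))
  list(subject = subj, states = states, stance = st)
}

# mirror a scenario through the sagittal (XZ) plane: negate all Y
mirror_scenario <- function(scn) {
  flip <- function(p) c(p[1], -p[2], p[3])
  states <- lapply(scn$states, function(s) {
    att <- s$attachment
    cord_state(cord_attachment(att$cord, flip(att$anchor), flip(att$belt)))
  })
  st <- stance(left = flip(scn$stance$right), right = flip(scn$stance$left))
  list(subject = scn$subject, states = states, stance = st)
}
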