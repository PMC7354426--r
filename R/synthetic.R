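# Synthetic bench-data generator: a parametric ground-truth tension curve
# plus a seeded noisy "dynamometer".

#' Parametric ground-truth cord tension curve
#'
#' A smooth, strictly increasing, saturating tension curve on 0--100%
#' elongation with value 0 at 0:
#' \deqn{F(x) = F_{max}\,(1 - e^{-(x/x_0)^p})}
#' The shape parameter `p` (> 1 gives a compliant toe region), the scale
#' `x0` (elongation percent at which the curve reaches 63% of saturation)
#' and the saturation force `Fmax` mimic the three-range behaviour of real
#' elastomer expanders: toe, quasi-linear rise, saturation.
#'
#' The named presets `"thick"` and `"thin"` are the ground truths behind
#' the packaged reference characteristics: their saturation levels are
#' calibrated so that the packaged worked scenarios reproduce the
#' documented unweighting levels (see [reference_characteristic()]).
#'
#' @param kind `"thick"`, `"thin"`, or `"custom"`.
#' @param fmax_N Saturation force in newtons (required for `"custom"`).
#' @param scale_pct Scale `x0` in elongation percent.
#' @param shape Toe shape exponent `p` (dimensionless, > 0).
#' @param grid Elongation grid in percent used by [generate_bench()];
#'   defaults to 21 points every 5% over 0--100%.
#' @return An object of class `synthetic_cord` with a `truth` function.
#' @export
synthetic_cord <- function(kind = c("thick", "thin", "custom"),
                           fmax_N = NULL, scale_pct = NULL, shape = NULL,
                           grid = seq(0, 100, by = 5)) {
  kind <- match.arg(kind)
  preset <- switch(kind,
    thick = list(fmax_N = .calib$thick$fmax_N, scale_pct = 55, shape = 1.6),
    thin = list(fmax_N = .calib$thin$fmax_N, scale_pct = 40, shape = 1.2),
    custom = list(fmax_N = fmax_N, scale_pct = scale_pct, shape = shape)
  )
  if (!is.null(fmax_N)) preset$fmax_N <- fmax_N
  if (!is.null(scale_pct)) preset$scale_pct <- scale_pct
  if (!is.null(shape)) preset$shape <- shape
  with(preset, {
    stopifnot(is.numeric(fmax_N), fmax_N > 0,
              is.numeric(scale_pct), scale_pct > 0,
              is.numeric(shape), shape > 0)
  })
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  if (any(grid < 0 | grid > 120)) {
    stop("`grid` elongations must lie in [0, 120]%", call. = FALSE)
  }
  truth <- local({
    fm <- preset$fmax_N; x0 <- preset$scale_pct; p <- preset$shape
    function(x) fm * (1 - exp(-(x / x0)^p))
  })
  structure(list(kind = kind, fmax_N = preset$fmax_N,
                 scale_pct = preset$scale_pct, shape = preset$shape,
                 grid = sort(as.numeric(grid)), truth = truth),
            class = "synthetic_cord")
}

# Saturation forces calibrated once from the packaged worked scenarios:
# per-cord tension T = u * m * g / (4 sin(angle)) at the scenario's
# elongation x_a, hence Fmax = T / (1 - exp(-(x_a/x0)^p)).
.calib_fmax <- function(u, mass_kg, angle_deg, elong_m, rest_m, x0, p) {
  t_anchor <- u * mass_kg * spider_gravity / (4 * sin(angle_deg * pi / 180))
  x_anchor <- 100 * elong_m / rest_m
  t_anchor / (1 - exp(-(x_anchor / x0)^p))
}

.calib <- list(
  # adult case: 15% unweighting of 75 kg, four cords at 45 deg, 250 mm
  thick = list(fmax_N = .calib_fmax(0.15, 75, 45, 0.250, 0.6175, 55, 1.6),
               scale_pct = 55, shape = 1.6, rest_m = 0.6175),
  # child case: 16% unweighting of 12 kg, four cords at 10 deg, 100 mm
  thin = list(fmax_N = .calib_fmax(0.16, 12, 10, 0.100, 0.6375, 40, 1.2),
              scale_pct = 40, shape = 1.2, rest_m = 0.6375)
)

#' Generate a synthetic bench measurement table
#'
#' Emulates a dynamometer bench session: the ground-truth tension is
#' sampled on the elongation grid and corrupted with multiplicative
#' Gaussian noise, `force = truth * (1 + e)`, `e ~ N(0, noise_cv)`,
#' floored at 0 N. Deterministic for a fixed seed.
#'
#' @param cord A [synthetic_cord()].
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 for noiseless samples).
#' @param seed Integer seed.
#' @return A bench table (`data.frame` with `elongation_pct`, `force_N`).
#' @examples
#' bench <- generate_bench(synthetic_cord("thin"), noise_cv = 0.01, seed = 42)
#' head(bench)
#' @export
generate_bench <- function(cord, noise_cv = 0, seed = 1) {
  stopifnot(inherits(cord, "synthetic_cord"))
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || noise_cv < 0) {
    stop("`noise_cv` must be a non-negative number", call. = FALSE)
  }
  x <- cord$grid
  f0 <- cord$truth(x)
  eps <- if (noise_cv > 0) {
    with_seed_(seed, stats::rnorm(length(x), 0, noise_cv))
  } else {
    numeric(length(x))
  }
  as_bench_table(data.frame(elongation_pct = x,
                            force_N = pmax(0, f0 * (1 + eps))))
}
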