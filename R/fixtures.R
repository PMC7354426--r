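# Packaged reference cord characteristics.

# regeneration parameters (also read by inst/scripts/regenerate-fixtures.R)
.fixture_params <- list(
  reference_adult_thick = list(kind = "thick", seed = 1234,
                               n_restarts = 40, grid_by = 1),
  reference_child_thin = list(kind = "thin", seed = 1234,
                              n_restarts = 40, grid_by = 1)
)

#' Packaged reference cord characteristics
#'
#' Two three-term sum-of-sines characteristics shipped with the package so
#' that every analysis is runnable without bench data. They are
#' *calibrated*, not measured: each was produced by fitting the
#' sum-of-sines model to a noiseless sample of the corresponding synthetic
#' ground-truth curve ([synthetic_cord()]), whose saturation level is
#' anchored so that the packaged worked scenarios reproduce their
#' documented unweighting levels:
#'
#' * `reference_adult_thick` — approx. 39.0 N at the 40.5% elongation of
#'   the adult scenario (75 kg, four cords at 45 degrees, 250 mm stretch,
#'   15% unweighting);
#' * `reference_child_thin` — approx. 27.1 N at the 15.7% elongation of
#'   the child scenario (12 kg, four cords at 10 degrees, 100 mm stretch,
#'   16% unweighting).
#'
#' Both are strictly increasing on 5--95% elongation. They make no claim
#' of fidelity to any physical cord's absolute stiffness.
#'
#' @param name `"reference_adult_thick"` or `"reference_child_thin"`.
#' @return A [cord_characteristic()].
#' @examples
#' ch <- reference_characteristic("reference_adult_thick")
#' tension(ch, 40.5)
#' @export
reference_characteristic <- function(name = c("reference_adult_thick",
                                              "reference_child_thin")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".json"),
                      package = "spiderstat", mustWork = TRUE)
  read_characteristic(path)
}

#' Rebuild a reference characteristic from its recorded recipe
#'
#' Reproduces a packaged fixture from scratch: samples the synthetic
#' ground truth noiselessly on a dense 1% grid and fits the three-term
#' sum-of-sines model with the recorded seed and restart count. Writing
#' the result with [write_characteristic()] reproduces the packaged JSON
#' bit-exactly. Used by the fixture regeneration script and the test
#' suite.
#'
#' @inheritParams reference_characteristic
#' @return A `cord_fit` (see [fit_sum_of_sines()]).
#' @export
build_reference_characteristic <- function(name = c("reference_adult_thick",
                                                    "reference_child_thin")) {
  name <- match.arg(name)
  p <- .fixture_params[[name]]
  sc <- synthetic_cord(p$kind, grid = seq(0, 100, by = p$grid_by))
  bench <- generate_bench(sc, noise_cv = 0)
  fit_sum_of_sines(bench, cord_spec(p$kind), n_restarts = p$n_restarts,
                   seed = p$seed)
}
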