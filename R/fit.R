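# Multi-start Levenberg-Marquardt fitting of the sum-of-sines model to
# bench force-elongation measurements.

# Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Validate a bench measurement table
#'
#' A bench table records one force reading per stretched position:
#' elongation in percent of rest length and force in newtons. The bench
#' protocol stretches the cord in fixed absolute steps (e.g. every 0.05 m)
#' but any single-pass grid is accepted.
#'
#' @param measurements A data frame with columns `elongation_pct` and
#'   `force_N`.
#' @return The validated data frame, invisibly classed `bench_table`.
#' @export
as_bench_table <- function(measurements) {
  m <- as.data.frame(measurements)
  if (!all(c("elongation_pct", "force_N") %in% names(m))) {
    stop("bench table needs columns `elongation_pct` and `force_N`",
         call. = FALSE)
  }
  if (any(!is.finite(m$elongation_pct)) || any(m$elongation_pct < 0) ||
      any(m$elongation_pct > 120)) {
    stop("`elongation_pct` must be finite and within [0, 120]",
         call. = FALSE)
  }
  if (any(!is.finite(m$force_N)) || any(m$force_N < 0)) {
    stop("`force_N` must be finite and non-negative", call. = FALSE)
  }
  class(m) <- c("bench_table", "data.frame")
  m
}

#' Read / write bench measurements as CSV
#'
#' Plain UTF-8 CSV with header `elongation_pct,force_N`, one row per
#' measurement, decimal point.
#'
#' @param path File path.
#' @param measurements A bench table (see [as_bench_table()]).
#' @export
read_bench <- function(path) {
  as_bench_table(utils::read.csv(path))
}

#' @rdname read_bench
#' @export
write_bench <- function(measurements, path) {
  m <- as_bench_table(measurements)
  utils::write.csv(m[, c("elongation_pct", "force_N")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit a three-term sum-of-sines tension model to bench data
#'
#' Least-squares fit of \eqn{T(x)=\sum_k a_k \sin(b_k x + c_k)} (three
#' terms) by Levenberg-Marquardt from multiple seeded random starting
#' points, keeping the restart with the smallest residual sum of squares.
#' The objective is multimodal in the frequencies, hence the multi-start:
#' initial amplitudes are drawn uniformly on (0, 2 max force], frequencies
#' on (0, pi/50] rad per percent (at most one full period over the 0-100%
#' domain), phases on \[-pi, pi\]. The fit is deterministic for a fixed
#' seed.
#'
#' @param measurements Bench table with at least 10 points spanning at
#'   least 50 percentage points of elongation.
#' @param spec A [cord_spec()] describing the measured cord.
#' @param n_restarts Number of random restarts (default 20).
#' @param seed Integer seed for the restart draws.
#' @return An object of class `cord_fit`: a list with `characteristic`
#'   (a [cord_characteristic()] carrying the coefficients and R-squared),
#'   `r_squared` (1 - SS_res/SS_tot about the observed mean), `residuals`
#'   (observed minus fitted, newtons), and `n_restarts_used`.
#' @examples
#' bench <- generate_bench(synthetic_cord("thin"), noise_cv = 0, seed = 1)
#' fit <- fit_sum_of_sines(bench, cord_spec("thin"), seed = 42)
#' fit$r_squared
#' @export
fit_sum_of_sines <- function(measurements, spec, n_restarts = 20, seed = 1) {
  m <- as_bench_table(measurements)
  stopifnot(inherits(spec, "cord_spec"), n_restarts >= 1)
  x <- m$elongation_pct
  y <- m$force_N
  if (nrow(m) < 10L) {
    stop("fit infeasible: need at least 10 bench measurements, got ",
         nrow(m), call. = FALSE)
  }
  if (diff(range(x)) < 50) {
    stop("fit infeasible: measurements must span at least 50 percentage ",
         "points of elongation", call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) {
    stop("fit infeasible: forces are constant (degenerate data)",
         call. = FALSE)
  }

  model <- function(p, x) {
    p[1] * sin(p[4] * x + p[7]) +
      p[2] * sin(p[5] * x + p[8]) +
      p[3] * sin(p[6] * x + p[9])
  }
  resid_fn <- function(p) y - model(p, x)

  fmax <- max(y)
  starts <- with_seed_(seed, {
    lapply(seq_len(n_restarts), function(i) {
      c(stats::runif(3, 0, 2 * fmax),          # amplitudes
        stats::runif(3, 1e-4, pi / 50),        # frequencies
        stats::runif(3, -pi, pi))              # phases
    })
  })

  best <- NULL
  best_ss <- Inf
  used <- 0L
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    used <- used + 1L
    ss <- sum(resid_fn(fit$par)^2)
    if (is.finite(ss) && ss < best_ss) {
      best_ss <- ss
      best <- fit$par
    }
  }
  if (is.null(best)) {
    stop("fit infeasible: no restart converged", call. = FALSE)
  }

  r2 <- 1 - best_ss / ss_tot
  char <- cord_characteristic(spec,
                              amplitudes = best[1:3],
                              frequencies = best[4:6],
                              phases = best[7:9],
                              r_squared = r2)
  structure(list(
    characteristic = char,
    r_squared = r2,
    residuals = resid_fn(best),
    n_restarts_used = used
  ), class = "cord_fit")
}

#' @export
print.cord_fit <- function(x, ...) {
  cat(sprintf("<cord_fit> R-squared %.6f (%d restarts used)\n",
              x$r_squared, x$n_restarts_used))
  print(x$characteristic)
  invisible(x)
}
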