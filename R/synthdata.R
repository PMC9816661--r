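#' Synthetic xenograft-style tumor-volume configuration
#'
#' Defines a ground-truth growth law plus a measurement design emulating a
#' breast-cancer xenograft volume study: replicate caliper measurements
#' every ~3 days, multiplicative lognormal noise, volumes rising sigmoidally
#' toward a plateau near 2,000 mm^3. The default generator is a von
#' Bertalanffy law with `gamma = 2/3` and plateau
#' `(alpha/beta)^(1/(1-gamma)) = 2000` mm^3.
#'
#' @param generator An [sm_params()] in mm^3 (defaults as above, starting
#'   from 100 mm^3).
#' @param times Measurement days.
#' @param n_replicates Replicate animals per time point.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise.
#' @param seed Default seed for [generate_growth_data()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(generator = sm_params(
                           "vb",
                           c(alpha = 0.15 * 2000^(1 / 3), beta = 0.15,
                             gamma = 2 / 3),
                           N0 = 100, unit = "mm3"),
                         times = seq(0, 36, by = 3),
                         n_replicates = 8,
                         noise_cv = 0.05,
                         seed = 1L) {
  check_that(noise_cv >= 0, "`noise_cv` must be >= 0")
  check_that(all(diff(times) > 0), "`times` must be increasing")
  check_that(n_replicates >= 1, "`n_replicates` must be >= 1")
  structure(list(generator = generator, times = as.numeric(times),
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic tumor-volume dataset
#'
#' Replicate curves are the generator trajectory multiplied, point-wise, by
#' unit-mean lognormal noise with coefficient of variation `noise_cv`; the
#' dataset records the replicate mean `z` and its standard error `sigma`
#' (floored by [growth_data()]). Because the noise is multiplicative, the
#' standard errors are estimated under a constant-CV variance model: the
#' replicate coefficient of variation is pooled across time points and
#' `sigma_i = cv_pooled * z_i / sqrt(n_replicates)`. Pooling stabilises the
#' weights (per-point standard errors from a handful of replicates are very
#' noisy, and weighting by them is known to distort chi-squared confidence
#' regions). The ground-truth parameters are attached as the `truth`
#' attribute.
#'
#' @param config A [synth_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return A [growth_data()] with `provenance = "synthetic"`.
#' @examples
#' dat <- generate_growth_data(synth_config(), seed = 7)
#' @export
generate_growth_data <- function(config, seed = config$seed) {
  set.seed(seed)
  gen <- config$generator
  traj <- sm_trajectory(gen$model, gen$values, gen$N0, config$times)
  check_that(!is.null(traj), "generator trajectory could not be computed")
  n_t <- length(config$times)
  reps <- config$n_replicates
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- matrix(rlnorm(n_t * reps, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = n_t)
  } else {
    noise <- matrix(1, nrow = n_t, ncol = reps)
  }
  curves <- traj * noise
  z <- rowMeans(curves)
  se <- if (reps > 1) {
    cv_pooled <- sqrt(mean((apply(curves, 1, sd) / z)^2))
    cv_pooled * z / sqrt(reps)
  } else {
    rep(0, n_t)
  }
  out <- growth_data(config$times, z, se, unit = gen$unit,
                     provenance = "synthetic")
  attr(out, "truth") <- gen
  attr(out, "replicates") <- curves
  out
}

#' ABM-generated reference dataset
#'
#' Runs the ABM at one `(p_div, div_lim)` point and aggregates the
#' replicate cancer-cell time-courses into a [growth_data()] (mean +/-
#' standard error), with iteration times converted to days. Used both for
#' the grid sweep and as pseudo-experimental ground truth in closure tests.
#'
#' @param p_div,div_lim ABM parameters for the runs.
#' @param reps Number of seeded replicates.
#' @param config Base [abm_config()] (its `p_div`/`div_lim` are
#'   overwritten).
#' @param seed Root seed; replicate r uses `seed + r`.
#' @return A [growth_data()] with `provenance = "abm"` and the runs in
#'   `attr(, "runs")`.
#' @export
generate_abm_reference <- function(p_div, div_lim, reps = 6,
                                   config = abm_config(),
                                   seed = config$seed) {
  cfg <- config
  cfg$p_div <- p_div
  cfg$div_lim <- as.integer(div_lim)
  validate_abm_config(cfg)
  runs <- abm_run_replicates(cfg, reps = reps, seed = seed)
  counts <- vapply(runs, function(r) r$series$n_cells, numeric(cfg$n_iterations))
  counts <- matrix(counts, nrow = cfg$n_iterations)
  z <- rowMeans(counts)
  se <- if (reps > 1) apply(counts, 1, sd) / sqrt(reps) else
    rep(0, cfg$n_iterations)
  days <- runs[[1]]$series$time_hours / 24
  out <- growth_data(days, z, se, unit = "cells", provenance = "abm")
  attr(out, "runs") <- runs
  out
}
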