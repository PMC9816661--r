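#' ABM configuration
#'
#' Builds a validated configuration for the on-lattice vascular tumor growth
#' simulator. Defaults are the baseline parameterisation of the model: a 1 mm
#' cubic domain discretised as a 50^3 tumor lattice (20 um site spacing) with
#' a 10-fold finer 500^3 vessel lattice, 20 stem + 80 progenitor cells seeded
#' in one corner, 8 mature boundary vessels, and 300 iterations of ~6 h each.
#' `p_div` (progenitor division probability per iteration) and `div_lim`
#' (divisions before senescence) are the calibration parameters of interest;
#' their defaults sit at the centre of the sampled ranges 0.05-0.245 and 8-15.
#'
#' @param p_div Progenitor division probability per iteration.
#' @param div_lim Maximum progenitor divisions before senescence (>= 1).
#' @param stem_div_prob Stem-cell division probability per iteration.
#' @param stem_symmetric_prob Probability a stem division is symmetric
#'   (stem + stem rather than stem + progenitor).
#' @param n_stem_init,n_prog_init Initial stem / progenitor cell counts.
#' @param n_vessels_init Initial number of mature boundary vessels.
#' @param high_migration_rate,low_migration_rate Cell migration rates, um/hour.
#' @param p_high_migratory_daughter Probability a daughter cell is
#'   high-migratory.
#' @param max_branch_prob Maximum vessel branching probability per iteration
#'   (attained when a hypoxic cell touches the vessel).
#' @param senescent_death_prob Senescent-cell death probability per iteration.
#' @param n_iterations Number of iterations to simulate.
#' @param hours_per_iteration Physical duration of one iteration, hours.
#' @param domain_side Cubic domain side, mm.
#' @param tumor_lattice_n,vessel_lattice_n Lattice sites per side (vessel
#'   lattice must be an integer refinement of the tumor lattice).
#' @param oxygen_radius Oxygen diffusion distance from perfused vessels, um;
#'   cells beyond it are hypoxic.
#' @param vegf_radius Distance over which hypoxic cells induce vessel
#'   branching, um.
#' @param tip_speed Sprout-tip migration speed, um per iteration.
#' @param anastomosis_radius Fusion distance for sprout tips, um.
#' @param hypoxic_div_factor Multiplier (in `[0, 1]`) applied to division
#'   probabilities of hypoxic cells.
#' @param seed Default root seed for [abm_run()].
#'
#' @return A list of class `abm_config`.
#' @examples
#' cfg <- abm_config(p_div = 0.245, div_lim = 8, n_iterations = 20)
#' @export
abm_config <- function(p_div = 0.125,
                       div_lim = 12,
                       stem_div_prob = 0.05,
                       stem_symmetric_prob = 0.05,
                       n_stem_init = 20,
                       n_prog_init = 80,
                       n_vessels_init = 8,
                       high_migration_rate = 8.3,
                       low_migration_rate = 0.83,
                       p_high_migratory_daughter = 0.05,
                       max_branch_prob = 0.2,
                       senescent_death_prob = 0.1,
                       n_iterations = 300,
                       hours_per_iteration = 6,
                       domain_side = 1,
                       tumor_lattice_n = 50,
                       vessel_lattice_n = 500,
                       oxygen_radius = 100,
                       vegf_radius = 200,
                       tip_speed = 20,
                       anastomosis_radius = 20,
                       hypoxic_div_factor = 0.5,
                       seed = 1L) {
  cfg <- list(
    p_div = p_div, div_lim = as.integer(div_lim),
    stem_div_prob = stem_div_prob,
    stem_symmetric_prob = stem_symmetric_prob,
    n_stem_init = as.integer(n_stem_init),
    n_prog_init = as.integer(n_prog_init),
    n_vessels_init = as.integer(n_vessels_init),
    high_migration_rate = high_migration_rate,
    low_migration_rate = low_migration_rate,
    p_high_migratory_daughter = p_high_migratory_daughter,
    max_branch_prob = max_branch_prob,
    senescent_death_prob = senescent_death_prob,
    n_iterations = as.integer(n_iterations),
    hours_per_iteration = hours_per_iteration,
    domain_side = domain_side,
    tumor_lattice_n = as.integer(tumor_lattice_n),
    vessel_lattice_n = as.integer(vessel_lattice_n),
    oxygen_radius = oxygen_radius,
    vegf_radius = vegf_radius,
    tip_speed = tip_speed,
    anastomosis_radius = anastomosis_radius,
    hypoxic_div_factor = hypoxic_div_factor,
    seed = as.integer(seed)
  )
  class(cfg) <- "abm_config"
  validate_abm_config(cfg)
  cfg
}

validate_abm_config <- function(cfg) {
  for (nm in c("p_div", "stem_div_prob", "stem_symmetric_prob",
               "p_high_migratory_daughter", "max_branch_prob",
               "senescent_death_prob", "hypoxic_div_factor")) {
    check_that(is_prob(cfg[[nm]]), paste0("`", nm, "` must be a probability in [0, 1]"))
  }
  check_that(is_count(cfg$div_lim) && cfg$div_lim >= 1, "`div_lim` must be an integer >= 1")
  for (nm in c("n_stem_init", "n_prog_init", "n_vessels_init", "n_iterations")) {
    check_that(is_count(cfg[[nm]]), paste0("`", nm, "` must be a non-negative count"))
  }
  for (nm in c("high_migration_rate", "low_migration_rate", "hours_per_iteration",
               "domain_side", "oxygen_radius", "vegf_radius", "tip_speed",
               "anastomosis_radius")) {
    check_that(is.numeric(cfg[[nm]]) && cfg[[nm]] >= 0, paste0("`", nm, "` must be >= 0"))
  }
  check_that(cfg$tumor_lattice_n >= 2 && cfg$vessel_lattice_n >= 2,
             "lattice sizes must be >= 2")
  check_that(cfg$vessel_lattice_n %% cfg$tumor_lattice_n == 0,
             "`vessel_lattice_n` must be an integer multiple of `tumor_lattice_n`")
  invisible(cfg)
}

#' Read / write ABM configurations as JSON
#'
#' The JSON keys match the [abm_config()] argument names exactly; missing keys
#' fall back to the defaults.
#'
#' @param path File path.
#' @param config An `abm_config`.
#' @return `read_abm_config()` returns an `abm_config`;
#'   `write_abm_config()` returns `path` invisibly.
#' @export
read_abm_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(abm_config))
  unknown <- setdiff(names(vals), known)
  check_that(length(unknown) == 0,
             paste("unknown config keys:", paste(unknown, collapse = ", ")))
  do.call(abm_config, vals)
}

#' @rdname read_abm_config
#' @export
write_abm_config <- function(config, path) {
  validate_abm_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.abm_config <- function(x, ...) {
  cat("<abm_config>\n")
  cat(sprintf("  p_div = %g, div_lim = %d; %d iterations of %g h\n",
              x$p_div, x$div_lim, x$n_iterations, x$hours_per_iteration))
  cat(sprintf("  lattice %d^3 (tumor) / %d^3 (vessel), domain %g mm\n",
              x$tumor_lattice_n, x$vessel_lattice_n, x$domain_side))
  cat(sprintf("  init: %d stem + %d progenitor cells, %d mature vessels\n",
              x$n_stem_init, x$n_prog_init, x$n_vessels_init))
  invisible(x)
}
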