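#' Pipeline configuration for the six-step calibration strategy
#'
#' Bundles everything the end-to-end run needs: the ABM parameter grid and
#' replicate count for the sweep, the candidate surrogate models, the
#' experimental dataset (real or synthetic), and the fitting / region
#' settings.
#'
#' @param p_div_values,div_lim_values Sampled grid values (>= 2 distinct
#'   values per axis; defaults are the sampled design
#'   `{0.05, 0.125, 0.245} x {8, 12, 15}`).
#' @param replicates ABM replicates per grid node (>= 2 so standard errors
#'   exist).
#' @param abm Base [abm_config()] shared by all nodes.
#' @param models Candidate surrogate models for selection.
#' @param experimental A [growth_data()] to calibrate against, or `NULL` to
#'   generate one from `synth` at run time.
#' @param synth A [synth_config()] used when `experimental` is `NULL`.
#' @param n_starts Multi-start count for fits.
#' @param n_beta_samples Number of `(beta, gamma)` pairs sampled along the
#'   identifiable combination.
#' @param region_grid Region mask resolution per axis.
#' @param seed Root seed.
#' @return A list of class `smore_config`.
#' @export
smore_config <- function(p_div_values = c(0.05, 0.125, 0.245),
                         div_lim_values = c(8, 12, 15),
                         replicates = 6,
                         abm = abm_config(),
                         models = c("vb", "gg", "gl"),
                         experimental = NULL,
                         synth = synth_config(),
                         n_starts = 20,
                         n_beta_samples = 25,
                         region_grid = 101,
                         seed = 1L) {
  check_that(length(unique(p_div_values)) >= 2 &&
               length(unique(div_lim_values)) >= 2,
             "need >= 2 distinct grid values per axis")
  check_that(replicates >= 2, "need >= 2 replicates per node for standard errors")
  structure(list(p_div_values = sort(unique(p_div_values)),
                 div_lim_values = sort(unique(div_lim_values)),
                 replicates = as.integer(replicates), abm = abm,
                 models = models, experimental = experimental,
                 synth = synth, n_starts = n_starts,
                 n_beta_samples = n_beta_samples,
                 region_grid = region_grid, seed = as.integer(seed)),
            class = "smore_config")
}

#' Step 2: ABM grid sweep
#'
#' Runs `replicates` seeded ABM simulations at every node of the
#' `(p_div, div_lim)` grid and aggregates each node into a
#' [growth_data()]. Node seeds are derived from the root seed so the sweep
#' is reproducible.
#'
#' @param config A [smore_config()].
#' @return A tibble with one row per node: `p_div`, `div_lim`, `data`
#'   (list-column of [growth_data()]).
#' @export
run_grid_sweep <- function(config) {
  grid <- expand.grid(p_div = config$p_div_values,
                      div_lim = config$div_lim_values)
  node_seed <- config$seed + 1000L * seq_len(nrow(grid))
  datasets <- purrr::map(seq_len(nrow(grid)), function(i) {
    generate_abm_reference(grid$p_div[i], grid$div_lim[i],
                           reps = config$replicates, config = config$abm,
                           seed = node_seed[i])
  })
  tibble::tibble(p_div = grid$p_div, div_lim = grid$div_lim,
                 data = datasets)
}

#' Step 4 helper: fit and profile the surrogate at every grid node
#'
#' Fits the chosen surrogate to each node dataset and profiles the named
#' parameters, returning one row per node x parameter with the 95% interval
#' — the discrete points on the confidence hypersurfaces.
#'
#' @param sweep A [run_grid_sweep()] tibble.
#' @param model Surrogate model id.
#' @param params Parameters to profile (default `beta` and `gamma`).
#' @param n_starts Multi-start count.
#' @param bounded_ci When a profile never crosses the threshold on one side
#'   (the parameter is practically unidentifiable there), substitute the
#'   edge of the explored parameter box for the missing bound instead of
#'   reporting `NA`. This widens the confidence band — a conservative
#'   choice that can only enlarge, never shrink, the admissible region
#'   inferred downstream.
#' @return A tibble with columns `p_div`, `div_lim`, `param`, `lower`,
#'   `mle`, `upper`, `chi2`, plus list-columns `fit` and `profile`.
#' @export
run_node_profiles <- function(sweep, model = "vb",
                              params = c("beta", "gamma"), n_starts = 20,
                              bounded_ci = FALSE) {
  rows <- purrr::map(seq_len(nrow(sweep)), function(i) {
    fit <- fit_growth(sweep$data[[i]], model = model, n_starts = n_starts)
    purrr::map(params, function(p) {
      prof <- profile_likelihood(fit, p)
      lo <- prof$ci_lower
      hi <- prof$ci_upper
      if (bounded_ci) {
        if (is.na(lo)) lo <- min(prof$profile$value)
        if (is.na(hi)) hi <- max(prof$profile$value)
      }
      tibble::tibble(p_div = sweep$p_div[i], div_lim = sweep$div_lim[i],
                     param = p, lower = lo, mle = prof$mle,
                     upper = hi, chi2 = fit$chi2,
                     fit = list(fit), profile = list(prof))
    }) %>% dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Run the full six-step calibration
#'
#' Steps 2-6 end to end: ABM grid sweep; surrogate model selection by
#' aggregate AIC over the node datasets (and the experimental data);
#' per-node fits and profile likelihoods; confidence-surface
#' reconstruction for `beta` and `gamma`; experimental fit, profiling and
#' identifiable-combination inference; and projection of the admissible
#' `(beta, gamma)` pairs into the data-consistent ABM parameter region.
#'
#' @param config A [smore_config()].
#' @param select Run model selection (otherwise the surrogate is fixed to
#'   `"vb"`).
#' @param bounded_ci Substitute explored-box edges for one-side-open
#'   profile intervals at grid nodes (see [run_node_profiles()]); the
#'   strict alternative (`FALSE`) errors when any node parameter is
#'   practically unidentifiable.
#' @return An object of class `smore_result` with elements `sweep`,
#'   `selection`, `model`, `nodes`, `surfaces`, `exp_fit`, `exp_profiles`,
#'   `combination`, `beta_range`, `region`.
#' @export
run_full <- function(config, select = TRUE, bounded_ci = TRUE) {
  set.seed(config$seed)
  exp_data <- config$experimental
  if (is.null(exp_data)) {
    exp_data <- generate_growth_data(config$synth,
                                     seed = config$seed + 500000L)
  }

  sweep <- run_grid_sweep(config)

  selection <- NULL
  model <- "vb"
  if (select) {
    datasets <- setNames(
      sweep$data,
      sprintf("abm_%g_%g", sweep$p_div, sweep$div_lim))
    datasets$experimental <- exp_data
    selection <- select_model(datasets, models = config$models,
                              n_starts = config$n_starts)
    model <- selection$best
  }

  nodes <- run_node_profiles(sweep, model = model,
                             n_starts = config$n_starts,
                             bounded_ci = bounded_ci)
  node_tbl <- surface_nodes(nodes)
  surf_beta <- confidence_surface(node_tbl, "beta")
  surf_gamma <- confidence_surface(node_tbl, "gamma")

  exp_fit <- fit_growth(exp_data, model = model, n_starts = config$n_starts)
  prof_beta <- profile_likelihood(exp_fit, "beta")
  prof_gamma <- profile_likelihood(exp_fit, "gamma")
  combination <- infer_combination(prof_beta)

  beta_range <- c(
    if (is.na(prof_beta$ci_lower)) combination$beta_range[1] else
      prof_beta$ci_lower,
    if (is.na(prof_beta$ci_upper)) combination$beta_range[2] else
      prof_beta$ci_upper)

  region <- infer_data_region(surf_beta, surf_gamma, combination,
                              beta_range = beta_range,
                              n_samples = config$n_beta_samples,
                              n_grid = config$region_grid)

  structure(
    list(sweep = sweep, selection = selection, model = model,
         nodes = nodes, surfaces = list(beta = surf_beta,
                                        gamma = surf_gamma),
         exp_data = exp_data, exp_fit = exp_fit,
         exp_profiles = list(beta = prof_beta, gamma = prof_gamma),
         combination = combination, beta_range = beta_range,
         region = region, config = config),
    class = "smore_result"
  )
}

#' @export
print.smore_result <- function(x, ...) {
  cat("<smore_result>\n")
  cat(sprintf("  surrogate: %s\n", x$model))
  cat(sprintf("  grid: %d nodes, %d replicates each\n", nrow(x$sweep),
              x$config$replicates))
  cat(sprintf("  combination: gamma = (beta + %.4g) / (beta + %.4g)\n",
              x$combination$a, x$combination$b))
  cat(sprintf("  admissible beta range: [%.4g, %.4g]\n", x$beta_range[1],
              x$beta_range[2]))
  cat(sprintf("  inferred region area fraction: %.3f\n",
              region_area(x$region)))
  invisible(x)
}

#' @export
glance.smore_result <- function(x, ...) {
  tibble::tibble(model = x$model, n_nodes = nrow(x$sweep),
                 beta_lower = x$beta_range[1], beta_upper = x$beta_range[2],
                 combo_a = x$combination$a, combo_b = x$combination$b,
                 region_area = region_area(x$region))
}
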