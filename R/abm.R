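#' Initialize the ABM state
#'
#' Seeds the tumor in one corner of the cubic domain and lays the initial
#' mature vasculature along the three boundary faces adjacent to that corner.
#' The `n_stem_init + n_prog_init` initial cells are packed into the smallest
#' cuboid of lattice sites at the origin corner (5 x 5 x 4 sites for the
#' default 100 cells), with stem cells interleaved uniformly through the
#' packing order. Mature vessels are straight full-length lines on the fine
#' lattice, perfused from the start; cells within `oxygen_radius` of a
#' perfused vessel site are normoxic, the rest hypoxic.
#'
#' Uses the current RNG stream (for the migratory-class draws); call
#' `set.seed()` first, or use [abm_run()] which seeds for you.
#'
#' @param config An [abm_config()].
#' @return An object of class `abm_state`.
#' @export
abm_initialize <- function(config) {
  validate_abm_config(config)
  nx <- config$tumor_lattice_n
  n_cells <- config$n_stem_init + config$n_prog_init

  pos <- corner_packing(n_cells, nx)
  stem_idx <- integer(0)
  if (config$n_stem_init > 0 && n_cells > 0) {
    stem_idx <- unique(round(seq(1, n_cells, length.out = config$n_stem_init)))
    # rounding can collapse indices when n_stem ~ n; top up deterministically
    extra <- setdiff(seq_len(n_cells), stem_idx)
    while (length(stem_idx) < config$n_stem_init) {
      stem_idx <- c(stem_idx, extra[1])
      extra <- extra[-1]
    }
  }
  phenotype <- rep(1L, n_cells)
  phenotype[stem_idx] <- 0L
  high_mig <- as.integer(runif(n_cells) < config$p_high_migratory_daughter)

  cells <- list(
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    phenotype = phenotype,
    divs = rep(0L, n_cells),
    high_mig = high_mig,
    senescent = rep(0L, n_cells),
    hypoxic = rep(0L, n_cells)
  )

  mature <- mature_vessel_layout(config)
  msites <- if (length(mature) > 0) {
    do.call(rbind, lapply(mature, `[[`, "sites"))
  } else {
    matrix(integer(0), ncol = 3)
  }
  mline <- rep(seq_along(mature),
               vapply(mature, function(v) nrow(v$sites), 1L))
  state <- structure(
    list(config = config, iteration = 0L, cells = cells,
         mature = mature, msites = msites, mline = as.integer(mline),
         chains = empty_chains(),
         csites = list(m = matrix(integer(0), ncol = 3), chain = integer(0)),
         oxy = NULL, cum_divisions = 0L,
         origin_um = initial_centroid_um(cells, config)),
    class = "abm_state"
  )
  state$oxy <- oxy_mask(perfused_fine_sites(state), config)
  state <- abm_classify_oxygenation(state)
  state
}

# Smallest cuboid packing of n sites at the origin corner; lexicographic fill.
corner_packing <- function(n, nx) {
  if (n == 0) return(matrix(integer(0), ncol = 3))
  dx <- ceiling(n^(1 / 3))
  dy <- ceiling(sqrt(n / dx))
  dz <- ceiling(n / (dx * dy))
  check_that(max(dx, dy, dz) <= nx,
             "initial cell count exceeds corner-region capacity")
  g <- expand.grid(x = seq_len(dx) - 1L, y = seq_len(dy) - 1L,
                   z = seq_len(dz) - 1L)
  g <- g[order(g$z, g$y, g$x), ]
  as.matrix(g[seq_len(n), , drop = FALSE])
}

# Straight mature vessels on the fine lattice, along the three boundary faces
# (x = 0, y = 0, z = 0) adjacent to the tumor corner. Offsets step away from
# the corner as more vessels are requested.
mature_vessel_layout <- function(config) {
  nf <- config$vessel_lattice_n
  base_off <- max(1L, round(0.1 * nf))
  # (fixed coordinate pattern, axis the vessel runs along)
  patterns <- list(
    list(fix = c(NA, 1, 0), along = 1L),  # z = 0 face, along x, y = offset
    list(fix = c(1, NA, 0), along = 2L),  # z = 0 face, along y, x = offset
    list(fix = c(NA, 0, 1), along = 1L),  # y = 0 face, along x, z = offset
    list(fix = c(1, 0, NA), along = 3L),  # y = 0 face, along z, x = offset
    list(fix = c(0, NA, 1), along = 2L),  # x = 0 face, along y, z = offset
    list(fix = c(0, 1, NA), along = 3L)   # x = 0 face, along z, y = offset
  )
  out <- vector("list", config$n_vessels_init)
  for (i in seq_len(config$n_vessels_init)) {
    pat <- patterns[[(i - 1L) %% 6L + 1L]]
    off <- min(base_off * (1L + 2L * ((i - 1L) %/% 6L)), nf - 1L)
    t_axis <- seq.int(0L, nf - 1L)
    sites <- matrix(0L, nrow = nf, ncol = 3)
    for (ax in 1:3) {
      sites[, ax] <- if (ax == pat$along) t_axis
      else if (is.na(pat$fix[ax])) off
      else pat$fix[ax] * 0L
    }
    out[[i]] <- list(p0 = sites[1, ], p1 = sites[nf, ], sites = sites)
  }
  out
}

initial_centroid_um <- function(cells, config) {
  if (length(cells$x) == 0) return(c(0, 0, 0))
  coarse_um(config) * c(mean(cells$x), mean(cells$y), mean(cells$z))
}

# All fine-lattice sites of perfused vasculature (mature + perfused chains).
perfused_fine_sites <- function(state) {
  sel <- state$chains$perfused[state$csites$chain]
  rbind(state$msites, state$csites$m[which(sel), , drop = FALSE])
}

# All vessel fine-lattice sites with owner annotation.
all_vessel_sites <- function(state) {
  m <- rbind(state$msites, state$csites$m)
  list(m = m,
       type = c(rep(0L, nrow(state$msites)),
                rep(1L, nrow(state$csites$m))),
       id = c(state$mline, state$csites$chain))
}

# Exact oxygenation mask: coarse sites within oxygen_radius (Euclidean, um)
# of any perfused fine-lattice vessel site.
oxy_mask <- function(fine_sites, config, base = NULL) {
  nx <- config$tumor_lattice_n
  if (is.null(base)) base <- logical(nx^3)
  if (nrow(fine_sites) == 0) return(base)
  cpp_oxy_dilate(as.integer(fine_sites[, 1]), as.integer(fine_sites[, 2]),
                 as.integer(fine_sites[, 3]), base, nx,
                 coarse_um(config), fine_um(config), config$oxygen_radius)
}

site_lin <- function(x, y, z, nx) 1L + x + nx * (y + nx * z)

#' Classify cell oxygenation
#'
#' Marks each cell normoxic if its Euclidean distance (in physical units) to
#' the nearest perfused vessel site is at most `oxygen_radius`, else hypoxic.
#' With `recompute = TRUE` the oxygenation mask is rebuilt from scratch from
#' the current perfused vasculature (otherwise the incrementally maintained
#' mask is used; the two are identical because perfusion only ever grows).
#'
#' @param state An `abm_state`.
#' @param recompute Rebuild the oxygenation mask from scratch.
#' @return The updated `abm_state`.
#' @export
abm_classify_oxygenation <- function(state, recompute = FALSE) {
  if (recompute) {
    state$oxy <- oxy_mask(perfused_fine_sites(state), state$config)
  }
  nx <- state$config$tumor_lattice_n
  cl <- state$cells
  if (length(cl$x) > 0) {
    lin <- site_lin(cl$x, cl$y, cl$z, nx)
    state$cells$hypoxic <- as.integer(!state$oxy[lin])
  }
  state
}

cells_phase <- function(state, divide, migrate, death) {
  cfg <- state$config
  cl <- state$cells
  sp <- coarse_um(cfg)
  res <- cpp_cells_phase(
    cl$x, cl$y, cl$z, cl$phenotype, cl$divs, cl$high_mig, cl$senescent,
    cl$hypoxic, state$oxy, cfg$tumor_lattice_n,
    cfg$p_div, cfg$stem_div_prob, cfg$stem_symmetric_prob,
    cfg$p_high_migratory_daughter, cfg$div_lim, cfg$hypoxic_div_factor,
    cfg$high_migration_rate * cfg$hours_per_iteration / sp,
    cfg$low_migration_rate * cfg$hours_per_iteration / sp,
    cfg$senescent_death_prob, divide, migrate, death
  )
  state$cells <- res[c("x", "y", "z", "phenotype", "divs", "high_mig",
                       "senescent", "hypoxic")]
  state$cum_divisions <- state$cum_divisions + res$n_divisions
  state$last_divisions <- res$n_divisions
  state$last_deaths <- res$n_deaths
  state
}

#' Elementary ABM operations
#'
#' Single-phase updates, mainly useful for testing and inspection; a full
#' iteration is [abm_step()]. `abm_attempt_divisions()` lets every
#' non-senescent cell divide with its phenotype- and oxygenation-dependent
#' probability into a uniformly chosen empty Moore neighbor;
#' `abm_attempt_migrations()` performs the per-iteration random-walk moves
#' (expected step count = rate x hours-per-iteration / site spacing, the
#' fractional part realised as a Bernoulli extra step).
#'
#' @param state An `abm_state` (oxygenation should be classified first).
#' @return The updated `abm_state`.
#' @export
abm_attempt_divisions <- function(state) cells_phase(state, TRUE, FALSE, FALSE)

#' @rdname abm_attempt_divisions
#' @export
abm_attempt_migrations <- function(state) cells_phase(state, FALSE, TRUE, FALSE)

#' One ABM iteration
#'
#' Executes, in order: perfusion update, oxygenation classification, vessel
#' sprouting / tip migration / anastomosis, cell divisions, cell migrations,
#' and senescent-cell death; then increments the iteration counter.
#'
#' @param state An `abm_state`.
#' @return The updated `abm_state`.
#' @export
abm_step <- function(state) {
  state <- update_perfusion(state)
  state <- abm_classify_oxygenation(state)
  state <- vasc_branch(state)
  state <- vasc_migrate_tips(state)
  state <- vasc_anastomose(state)
  state <- cells_phase(state, TRUE, TRUE, TRUE)
  state$iteration <- state$iteration + 1L
  state
}

#' Run a seeded ABM simulation
#'
#' @param config An [abm_config()].
#' @param seed Integer seed (defaults to `config$seed`). Identical config and
#'   seed give bit-identical results.
#' @return An object of class `abm_run` with elements `series` (one row per
#'   iteration: `iteration`, `time_hours`, `n_cells`, `n_hypoxic`, `n_stem`,
#'   `cum_divisions`), `cells` and `vessels` (final-snapshot tibbles),
#'   `origin_um`, `config` and `seed`.
#' @examples
#' run <- abm_run(abm_config(n_iterations = 5), seed = 1)
#' run$series
#' @export
abm_run <- function(config, seed = config$seed) {
  set.seed(seed)
  state <- abm_initialize(config)
  n <- config$n_iterations
  rec <- matrix(0L, nrow = n, ncol = 4)
  for (i in seq_len(n)) {
    state <- abm_step(state)
    cl <- state$cells
    rec[i, ] <- c(length(cl$x), sum(cl$hypoxic), sum(cl$phenotype == 0L),
                  state$cum_divisions)
  }
  series <- tibble::tibble(
    iteration = seq_len(n),
    time_hours = seq_len(n) * config$hours_per_iteration,
    n_cells = rec[, 1], n_hypoxic = rec[, 2], n_stem = rec[, 3],
    cum_divisions = rec[, 4]
  )
  structure(
    list(series = series,
         cells = snapshot_cells(state),
         vessels = snapshot_vessels(state),
         origin_um = state$origin_um,
         config = config, seed = seed,
         final_state = state),
    class = "abm_run"
  )
}

snapshot_cells <- function(state) {
  cl <- state$cells
  tibble::tibble(
    x = cl$x, y = cl$y, z = cl$z,
    phenotype = ifelse(cl$phenotype == 0L, "stem", "progenitor"),
    migratory_class = ifelse(cl$high_mig == 1L, "high", "low"),
    status = ifelse(cl$hypoxic == 1L, "hypoxic", "normoxic"),
    senescent = cl$senescent == 1L,
    divisions_used = cl$divs
  )
}

snapshot_vessels <- function(state) {
  vs <- all_vessel_sites(state)
  if (nrow(vs$m) == 0) {
    return(tibble::tibble(x = integer(0), y = integer(0), z = integer(0),
                          perfused = logical(0)))
  }
  perf <- vs$type == 0L
  idx <- which(vs$type == 1L)
  if (length(idx) > 0) perf[idx] <- state$chains$perfused[vs$id[idx]]
  tibble::tibble(x = vs$m[, 1], y = vs$m[, 2], z = vs$m[, 3],
                 perfused = as.logical(perf))
}

#' @export
print.abm_run <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("<abm_run> %d iterations, seed %d\n", n, x$seed))
  if (n > 0) {
    last <- x$series[n, ]
    cat(sprintf("  final: %d cells (%d hypoxic, %d stem), %d divisions\n",
                last$n_cells, last$n_hypoxic, last$n_stem,
                last$cum_divisions))
  }
  cat(sprintf("  vasculature: %d fine-lattice sites (%d perfused)\n",
              nrow(x$vessels), sum(x$vessels$perfused)))
  invisible(x)
}

#' Replicated ABM runs
#'
#' Runs the simulator `reps` times with derived seeds `seed + 1 ... seed +
#' reps`.
#'
#' @inheritParams abm_run
#' @param reps Number of replicates.
#' @return A list of `abm_run` objects.
#' @export
abm_run_replicates <- function(config, reps, seed = config$seed) {
  lapply(seq_len(reps), function(r) abm_run(config, seed = seed + r))
}

#' Tidy an ABM run
#'
#' @param x An `abm_run`.
#' @param ... Unused.
#' @return The per-iteration time series as a tibble.
#' @export
tidy.abm_run <- function(x, ...) x$series

#' @export
glance.abm_run <- function(x, ...) {
  n <- nrow(x$series)
  tibble::tibble(
    n_iterations = n,
    final_cells = if (n) x$series$n_cells[n] else NA_integer_,
    final_hypoxic = if (n) x$series$n_hypoxic[n] else NA_integer_,
    final_stem = if (n) x$series$n_stem[n] else NA_integer_,
    cum_divisions = if (n) x$series$cum_divisions[n] else NA_integer_,
    n_vessel_sites = nrow(x$vessels),
    seed = x$seed
  )
}

#' Plot an ABM run time series
#'
#' @param object An `abm_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abm_run <- function(object, ...) {
  df <- tidyr::pivot_longer(object$series,
                            c("n_cells", "n_hypoxic", "n_stem"),
                            names_to = "population", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_hours / 24,
                                   y = .data$count,
                                   colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "cells",
                  title = sprintf("ABM run (p_div = %g, div_lim = %d)",
                                  object$config$p_div, object$config$div_lim))
}
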