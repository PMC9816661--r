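#' Admissible ABM parameter region for one surrogate parameter value
#'
#' The region of the `(p_div, div_lim)` rectangle where a surrogate
#' parameter value `s` lies between the lower and upper confidence surfaces:
#' the projection of the data-admissible surrogate value back onto ABM
#' parameter space.
#'
#' @param surface A [confidence_surface()].
#' @param s Surrogate parameter value (finite scalar).
#' @param n_grid Grid resolution per axis (`n_grid x n_grid` mask).
#' @return An object of class `param_region`: `p_div`/`div_lim` grid
#'   vectors, logical `mask` matrix (`p_div` on rows), and a `provenance`
#'   list of the constraints applied.
#' @export
admissible_region <- function(surface, s, n_grid = 101) {
  check_that(is.numeric(s) && length(s) == 1 && is.finite(s),
             "`s` must be a finite scalar")
  px <- seq(min(surface$p_div), max(surface$p_div), length.out = n_grid)
  py <- seq(min(surface$div_lim), max(surface$div_lim), length.out = n_grid)
  g <- expand.grid(p_div = px, div_lim = py)
  ev <- surface_eval(surface, g$p_div, g$div_lim)
  mask <- matrix(ev$lower <= s & s <= ev$upper, nrow = n_grid)
  new_param_region(px, py, mask,
                   provenance = list(list(param = surface$param, value = s)))
}

new_param_region <- function(p_div, div_lim, mask, provenance = list()) {
  structure(list(p_div = p_div, div_lim = div_lim, mask = mask,
                 provenance = provenance),
            class = "param_region")
}

check_same_grid <- function(a, b) {
  check_that(inherits(a, "param_region") && inherits(b, "param_region"),
             "arguments must be param_region objects")
  check_that(isTRUE(all.equal(a$p_div, b$p_div)) &&
               isTRUE(all.equal(a$div_lim, b$div_lim)),
             "regions are defined on different grids")
}

#' Combine parameter regions
#'
#' `region_intersect()` is the logical AND of the masks (the ABM region
#' consistent with *all* the constraints); `region_union()` is the logical
#' OR (consistent with *any* of them). All regions must share one grid.
#'
#' @param ... `param_region` objects (or a single list of them).
#' @return A `param_region`.
#' @export
region_intersect <- function(...) {
  regions <- flatten_regions(list(...))
  out <- regions[[1]]
  for (r in regions[-1]) {
    check_same_grid(out, r)
    out$mask <- out$mask & r$mask
    out$provenance <- c(out$provenance, r$provenance)
  }
  out
}

#' @rdname region_intersect
#' @export
region_union <- function(...) {
  regions <- flatten_regions(list(...))
  out <- regions[[1]]
  for (r in regions[-1]) {
    check_same_grid(out, r)
    out$mask <- out$mask | r$mask
    out$provenance <- c(out$provenance, r$provenance)
  }
  out
}

flatten_regions <- function(args) {
  if (length(args) == 1 && !inherits(args[[1]], "param_region")) {
    args <- args[[1]]
  }
  check_that(length(args) >= 1, "need at least one region")
  args
}

#' Area fraction of a region
#'
#' @param region A `param_region`.
#' @return Fraction of the rectangle covered (mean of the mask).
#' @export
region_area <- function(region) mean(region$mask)

#' Infer the experiment-consistent ABM parameter region
#'
#' Samples `n_samples` values of `beta` across `beta_range`, computes the
#' paired `gamma` through the identifiable combination
#' `gamma = (beta + a)/(beta + b)`, intersects the per-parameter admissible
#' regions for each pair, and returns the union over pairs: the region of
#' ABM parameter space consistent with the experimental data.
#'
#' @param surface_beta,surface_gamma [confidence_surface()]s for `beta` and
#'   `gamma`.
#' @param combo An [infer_combination()] result (or any object with `a`,
#'   `b`).
#' @param beta_range Length-2 range of admissible `beta` values.
#' @param n_samples Number of evenly spaced `beta` samples.
#' @param n_grid Region grid resolution.
#' @return A `param_region` (the union), with the sampled pairs in
#'   `attr(, "pairs")`.
#' @export
infer_data_region <- function(surface_beta, surface_gamma, combo,
                              beta_range, n_samples = 25, n_grid = 101) {
  check_that(length(beta_range) == 2 && all(is.finite(beta_range)) &&
               beta_range[1] <= beta_range[2],
             "`beta_range` must be a finite increasing length-2 range")
  betas <- if (n_samples == 1) mean(beta_range) else
    seq(beta_range[1], beta_range[2], length.out = n_samples)
  gammas <- (betas + combo$a) / (betas + combo$b)
  pieces <- purrr::map2(betas, gammas, function(b, g) {
    region_intersect(admissible_region(surface_beta, b, n_grid = n_grid),
                     admissible_region(surface_gamma, g, n_grid = n_grid))
  })
  out <- region_union(pieces)
  attr(out, "pairs") <- tibble::tibble(beta = betas, gamma = gammas)
  out
}

#' Membership test for a parameter point
#'
#' @param region A `param_region`.
#' @param p_div,div_lim Query point.
#' @return Logical: is the nearest grid point inside the region?
#' @export
region_contains <- function(region, p_div, div_lim) {
  ix <- which.min(abs(region$p_div - p_div))
  iy <- which.min(abs(region$div_lim - div_lim))
  region$mask[ix, iy]
}

#' @export
print.param_region <- function(x, ...) {
  cat(sprintf(
    "<param_region> %d x %d grid on [%g, %g] x [%g, %g]; area fraction %.3f\n",
    length(x$p_div), length(x$div_lim), min(x$p_div), max(x$p_div),
    min(x$div_lim), max(x$div_lim), region_area(x)))
  invisible(x)
}

#' Tidy a parameter region
#'
#' @param x A `param_region`.
#' @param integer_div_lim Also flag rows whose `div_lim` is (near-)integer —
#'   the directly ABM-checkable subset.
#' @param ... Unused.
#' @return A tibble with columns `p_div`, `div_lim`, `admissible` (and
#'   `integer_div_lim` if requested).
#' @export
tidy.param_region <- function(x, integer_div_lim = FALSE, ...) {
  g <- expand.grid(p_div = x$p_div, div_lim = x$div_lim)
  out <- tibble::tibble(p_div = g$p_div, div_lim = g$div_lim,
                        admissible = as.vector(x$mask))
  if (integer_div_lim) {
    out$integer_div_lim <- abs(out$div_lim - round(out$div_lim)) < 1e-9
  }
  out
}

#' @export
glance.param_region <- function(x, ...) {
  inside <- tidy(x) %>% dplyr::filter(.data$admissible)
  tibble::tibble(
    area_fraction = region_area(x),
    p_div_min = if (nrow(inside)) min(inside$p_div) else NA_real_,
    p_div_max = if (nrow(inside)) max(inside$p_div) else NA_real_,
    div_lim_min = if (nrow(inside)) min(inside$div_lim) else NA_real_,
    div_lim_max = if (nrow(inside)) max(inside$div_lim) else NA_real_
  )
}

#' Plot a parameter region
#'
#' @param object A `param_region`.
#' @param ... Unused.
#' @export
autoplot.param_region <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_div, y = .data$div_lim,
                                   fill = .data$admissible)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90",
                                          `TRUE` = "orange")) +
    ggplot2::labs(x = "p_div", y = "div_lim", fill = "admissible")
}

#' Write a region to CSV (grid + mask)
#'
#' @param region A `param_region`.
#' @param path Output CSV path.
#' @export
write_region <- function(region, path) {
  utils::write.csv(tidy(region), path, row.names = FALSE)
  invisible(path)
}
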