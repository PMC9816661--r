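#' Collect confidence-surface nodes from per-node profiles
#'
#' Each sampled ABM parameter combination contributes, per surrogate
#' parameter, one node carrying the profile-likelihood 95% interval
#' (`lower`, `upper`) around the estimate (`mle`). Open-ended (practically
#' unidentifiable) intervals are rejected: the surfaces need finite bounds
#' everywhere on the grid.
#'
#' @param profiles A tibble (or data frame) with columns `p_div`, `div_lim`,
#'   `param`, `lower`, `mle`, `upper` — typically built by mapping
#'   [profile_likelihood()] over grid-node fits (see [run_node_profiles()]).
#' @return A tibble of surface nodes (class `surface_nodes`).
#' @export
surface_nodes <- function(profiles) {
  df <- tibble::as_tibble(profiles)
  need <- c("p_div", "div_lim", "param", "lower", "mle", "upper")
  check_that(all(need %in% names(df)),
             paste("profiles need columns:", paste(need, collapse = ", ")))
  bad <- !is.finite(df$lower) | !is.finite(df$upper)
  if (any(bad)) {
    rlang::abort(paste0(
      "open-ended confidence interval at node(s) ",
      paste(sprintf("(%g, %g, %s)", df$p_div[bad], df$div_lim[bad],
                    df$param[bad]), collapse = ", "),
      "; enrich the ABM data or refine the profile grid"))
  }
  ok <- df$lower <= df$mle & df$mle <= df$upper
  if (!all(ok)) {
    rlang::abort("node(s) violate lower <= mle <= upper")
  }
  out <- df[, need]
  class(out) <- c("surface_nodes", class(out))
  out
}

#' Build a confidence surface over the ABM parameter plane
#'
#' Bilinear interpolation of the lower and upper 95% bounds of one surrogate
#' parameter over the sampled `(p_div, div_lim)` rectangle. The nodes must
#' form a complete rectangular grid (irregular spacing is fine); `div_lim`
#' is treated as continuous. No extrapolation outside the node rectangle.
#'
#' @param nodes A [surface_nodes()] tibble (may contain several parameters).
#' @param param Which surrogate parameter to build the surface for.
#' @return An object of class `conf_surface` with node coordinate vectors
#'   and `lower`/`mle`/`upper` node matrices.
#' @export
confidence_surface <- function(nodes, param) {
  df <- dplyr::filter(tibble::as_tibble(nodes), .data$param == !!param)
  check_that(nrow(df) > 0, paste0("no nodes for parameter `", param, "`"))
  xs <- sort(unique(df$p_div))
  ys <- sort(unique(df$div_lim))
  check_that(length(xs) >= 2 && length(ys) >= 2,
             "need at least a 2 x 2 node grid")
  check_that(nrow(df) == length(xs) * length(ys) &&
               !anyDuplicated(df[, c("p_div", "div_lim")]),
             "nodes must form a complete rectangular grid")
  shape <- function(col) {
    m <- matrix(NA_real_, length(xs), length(ys))
    m[cbind(match(df$p_div, xs), match(df$div_lim, ys))] <- df[[col]]
    m
  }
  structure(
    list(param = param, p_div = xs, div_lim = ys,
         lower = shape("lower"), mle = shape("mle"), upper = shape("upper")),
    class = "conf_surface"
  )
}

# Bilinear interpolation on an irregular rectilinear grid; exact at nodes,
# reproduces affine functions.
bilinear_eval <- function(xs, ys, zmat, x, y) {
  check_that(all(x >= min(xs) - 1e-12) && all(x <= max(xs) + 1e-12) &&
               all(y >= min(ys) - 1e-12) && all(y <= max(ys) + 1e-12),
             "query outside the node rectangle (no extrapolation)")
  x <- pmin(pmax(x, min(xs)), max(xs))
  y <- pmin(pmax(y, min(ys)), max(ys))
  ix <- pmin(pmax(findInterval(x, xs), 1L), length(xs) - 1L)
  iy <- pmin(pmax(findInterval(y, ys), 1L), length(ys) - 1L)
  x0 <- xs[ix]; x1 <- xs[ix + 1L]
  y0 <- ys[iy]; y1 <- ys[iy + 1L]
  tx <- (x - x0) / (x1 - x0)
  ty <- (y - y0) / (y1 - y0)
  z00 <- zmat[cbind(ix, iy)]
  z10 <- zmat[cbind(ix + 1L, iy)]
  z01 <- zmat[cbind(ix, iy + 1L)]
  z11 <- zmat[cbind(ix + 1L, iy + 1L)]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}

#' Evaluate a confidence surface
#'
#' @param surface A [confidence_surface()].
#' @param p_div,div_lim Query coordinates (vectorised; must lie inside the
#'   node rectangle).
#' @return A tibble with columns `p_div`, `div_lim`, `lower`, `mle`,
#'   `upper`.
#' @export
surface_eval <- function(surface, p_div, div_lim) {
  check_that(inherits(surface, "conf_surface"), "`surface` must be a conf_surface")
  tibble::tibble(
    p_div = p_div, div_lim = div_lim,
    lower = bilinear_eval(surface$p_div, surface$div_lim, surface$lower,
                          p_div, div_lim),
    mle = bilinear_eval(surface$p_div, surface$div_lim, surface$mle,
                        p_div, div_lim),
    upper = bilinear_eval(surface$p_div, surface$div_lim, surface$upper,
                          p_div, div_lim)
  )
}

#' @export
print.conf_surface <- function(x, ...) {
  cat(sprintf(
    "<conf_surface> %s on [%g, %g] x [%g, %g] (%d x %d nodes)\n",
    x$param, min(x$p_div), max(x$p_div), min(x$div_lim), max(x$div_lim),
    length(x$p_div), length(x$div_lim)))
  invisible(x)
}

#' @export
tidy.conf_surface <- function(x, ...) {
  g <- expand.grid(p_div = x$p_div, div_lim = x$div_lim)
  tibble::tibble(p_div = g$p_div, div_lim = g$div_lim,
                 param = x$param,
                 lower = as.vector(x$lower), mle = as.vector(x$mle),
                 upper = as.vector(x$upper))
}

#' Plot a confidence surface as filled bands
#'
#' @param object A `conf_surface`.
#' @param n Grid resolution per axis.
#' @param ... Unused.
#' @export
autoplot.conf_surface <- function(object, n = 60, ...) {
  g <- expand.grid(
    p_div = seq(min(object$p_div), max(object$p_div), length.out = n),
    div_lim = seq(min(object$div_lim), max(object$div_lim), length.out = n))
  ev <- surface_eval(object, g$p_div, g$div_lim)
  ev$width <- ev$upper - ev$lower
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$p_div, y = .data$div_lim,
                                   fill = .data$width)) +
    ggplot2::geom_raster() +
    ggplot2::labs(title = sprintf("95%% band width for %s", object$param),
                  fill = "width")
}

#' Serialise confidence surfaces to JSON
#'
#' @param surfaces A named list of [confidence_surface()] objects.
#' @param path Output path.
#' @export
write_surfaces <- function(surfaces, path) {
  payload <- lapply(surfaces, function(s) {
    list(param = s$param, p_div = s$p_div, div_lim = s$div_lim,
         lower = s$lower, mle = s$mle, upper = s$upper)
  })
  jsonlite::write_json(payload, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_surfaces
#' @export
read_surfaces <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload, function(s) {
    structure(list(param = s$param, p_div = s$p_div, div_lim = s$div_lim,
                   lower = as.matrix(s$lower), mle = as.matrix(s$mle),
                   upper = as.matrix(s$upper)),
              class = "conf_surface")
  })
}
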