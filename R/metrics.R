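#' Distance of the farthest cancer cell from the initial tumor
#'
#' @param cells Final-snapshot cell tibble (columns `x`, `y`, `z`, lattice
#'   coordinates) or a 3-column matrix.
#' @param origin Tumor centroid at initiation, physical units (um).
#' @param spacing Lattice spacing in um (20 at the defaults).
#' @return Maximum Euclidean distance in um.
#' @export
farthest_cell_distance <- function(cells, origin = c(0, 0, 0), spacing = 20) {
  m <- as_xyz_matrix(cells)
  check_that(nrow(m) > 0, "empty snapshot")
  sqrt(max(dist2_point_rows(origin, m * spacing)))
}

as_xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    check_that(ncol(x) == 3, "need a 3-column matrix")
    return(x)
  }
  check_that(all(c("x", "y", "z") %in% names(x)), "need columns x, y, z")
  cbind(x$x, x$y, x$z)
}

#' Box-counting fractal dimension of a 3D point set
#'
#' Counts occupied boxes `N(eps)` over a dyadic sequence of box sizes and
#' returns the least-squares slope of `-log N(eps)` versus `log eps` — the
#' box-counting (Minkowski) dimension of the occupied-site set. Default box
#' sizes are `1, 2, 4, ...` lattice units up to a quarter of the occupied
#' bounding box.
#'
#' @param points Integer lattice coordinates (matrix or tibble with
#'   `x`,`y`,`z`), e.g. the occupied fine-lattice vasculature sites.
#' @param box_sizes Box edge lengths (lattice units); must have >= 2 values
#'   after defaulting.
#' @param min_points Minimum occupied sites required.
#' @return The fitted dimension (scalar), with the per-size counts in
#'   `attr(, "counts")`.
#' @export
box_count_dimension <- function(points, box_sizes = NULL, min_points = 100) {
  m <- as_xyz_matrix(points)
  m <- unique(m)
  check_that(nrow(m) >= max(2, min_points),
             sprintf("need at least %d distinct occupied sites", max(2, min_points)))
  m <- sweep(m, 2, apply(m, 2, min))  # translate to the origin
  extent <- max(apply(m, 2, max)) + 1
  if (is.null(box_sizes)) {
    emax <- max(1, extent / 4)
    box_sizes <- 2^(0:floor(log2(emax)))
  }
  box_sizes <- sort(unique(box_sizes))
  check_that(length(box_sizes) >= 2, "need at least two box sizes")
  counts <- vapply(box_sizes, function(e) {
    b <- floor(m / e)
    nrow(unique(b))
  }, 1)
  fit <- lm(y ~ x, data = data.frame(x = log(box_sizes), y = -log(counts)))
  dim <- unname(coef(fit)[2])
  attr(dim, "counts") <- tibble::tibble(box_size = box_sizes,
                                        n_boxes = counts)
  dim
}

#' Connected-component filtering of a voxel mask
#'
#' Removes 26-connected components with fewer than `threshold` voxels —
#' satellites of cells that migrated away from the primary tumor mass.
#' Components with exactly `threshold` voxels are retained (strict `<`).
#'
#' @param points Integer voxel coordinates (matrix or tibble `x`,`y`,`z`).
#' @param threshold Minimum voxel count for a component to be kept.
#' @return The retained voxels, same representation as the input matrix.
#' @export
filter_small_components <- function(points, threshold = 50) {
  m <- unique(as_xyz_matrix(points))
  n <- nrow(m)
  if (n == 0 || threshold <= 1) return(m)
  span <- apply(m, 2, function(v) diff(range(v))) + 3L
  mm <- sweep(m, 2, apply(m, 2, min)) + 1L  # 1-based, padded
  key <- mm[, 1] + span[1] * (mm[, 2] + span[2] * mm[, 3])
  idx <- seq_len(n)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    nb_key <- (mm[, 1] + offs[k, 1]) +
      span[1] * ((mm[, 2] + offs[k, 2]) + span[2] * (mm[, 3] + offs[k, 3]))
    j <- match(nb_key, key)
    hit <- which(!is.na(j) & idx < j)
    if (length(hit)) edges[[length(edges) + 1L]] <- cbind(idx[hit], j[hit])
  }
  if (length(edges) == 0) {
    comp <- seq_len(n)  # all singletons
    sizes <- rep(1L, n)
    keep <- sizes[comp] >= threshold
    return(m[keep, , drop = FALSE])
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  cmp <- igraph::components(g)
  keep <- cmp$csize[cmp$membership] >= threshold
  m[keep, , drop = FALSE]
}

#' Tumor enclosing-surface area and volume
#'
#' Filters out small disconnected cell clusters
#' ([filter_small_components()], cutoff `component_threshold` voxels), then
#' computes the surface area and volume of the convex hull enclosing the
#' corner points of the remaining voxels (each voxel contributes its 8
#' corners at +/- half a spacing, so a solid block recovers its physical
#' dimensions).
#'
#' @param cells Voxel coordinates of cancer cells (matrix or tibble).
#' @param component_threshold Small-component cutoff (voxels).
#' @param spacing Voxel spacing, um.
#' @return A list with `surface_area` (um^2), `volume` (um^3) and
#'   `n_voxels` retained.
#' @export
tumor_surface_volume <- function(cells, component_threshold = 50,
                                 spacing = 20) {
  m <- filter_small_components(cells, component_threshold)
  check_that(nrow(m) > 0, "no voxels survive component filtering")
  cand <- extremal_voxels(m)
  corners <- voxel_corners(cand) * spacing
  hull <- cpp_convex_hull(corners)
  check_that(isTRUE(hull$ok), "degenerate voxel set: convex hull failed")
  list(surface_area = hull$area, volume = hull$volume, n_voxels = nrow(m))
}

# Voxels extremal along some axis line; every convex-hull vertex is among
# them, so the hull input shrinks from O(volume) to O(surface).
extremal_voxels <- function(m) {
  keep <- rep(FALSE, nrow(m))
  axes <- list(c(2, 3, 1), c(1, 3, 2), c(1, 2, 3))
  for (ax in axes) {
    key <- paste(m[, ax[1]], m[, ax[2]])
    v <- m[, ax[3]]
    lo <- tapply(v, key, min)[key]
    hi <- tapply(v, key, max)[key]
    keep <- keep | v == lo | v == hi
  }
  m[keep, , drop = FALSE]
}

voxel_corners <- function(m) {
  offs <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5)))
  out <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
    sweep(m, 2, -offs[k, ])
  }))
  unique(out)
}

#' Compactness of a 3D shape
#'
#' Dimensionless sphericity score `(36 pi)^(1/6) Vol^(1/3) / sqrt(SA)`,
#' equal to 1 for a perfect sphere and smaller for irregular shapes. The
#' `literal = TRUE` variant computes `Vol^(1/3) (36 pi)^(1/6) / SA`
#' (a non-dimensionless form that appears in parts of the shape-analysis
#' literature; not recommended).
#'
#' @param surface_area Surface area (> 0).
#' @param volume Volume (> 0).
#' @param literal Use the non-dimensionless variant.
#' @return Compactness (scalar).
#' @examples
#' r <- 5
#' compactness(4 * pi * r^2, 4 / 3 * pi * r^3)  # 1
#' @export
compactness <- function(surface_area, volume, literal = FALSE) {
  check_that(is_pos(surface_area) && is_pos(volume),
             "`surface_area` and `volume` must be > 0")
  if (literal) {
    volume^(1 / 3) * (36 * pi)^(1 / 6) / surface_area
  } else {
    (36 * pi)^(1 / 6) * volume^(1 / 3) / sqrt(surface_area)
  }
}

#' All morphology metrics for one ABM run
#'
#' @param run An [abm_run()].
#' @param component_threshold Small-component cutoff for the tumor surface.
#' @param box_sizes Optional box sizes for the vasculature fractal
#'   dimension.
#' @return A one-row tibble: `farthest_distance_um`, `fractal_dimension`,
#'   `surface_area_um2`, `volume_um3`, `sa_to_vol`, `compactness`.
#' @export
tumor_shape_metrics <- function(run, component_threshold = 50,
                                box_sizes = NULL) {
  cfg <- run$config
  sp <- coarse_um(cfg)
  sv <- tumor_surface_volume(run$cells, component_threshold, spacing = sp)
  fd <- tryCatch(box_count_dimension(run$vessels, box_sizes = box_sizes),
                 error = function(e) NA_real_)
  tibble::tibble(
    farthest_distance_um = farthest_cell_distance(run$cells, run$origin_um,
                                                  spacing = sp),
    fractal_dimension = as.numeric(fd),
    surface_area_um2 = sv$surface_area,
    volume_um3 = sv$volume,
    sa_to_vol = sv$surface_area / sv$volume,
    compactness = compactness(sv$surface_area, sv$volume)
  )
}

#' Compare a morphology metric between two ABM parameter sets
#'
#' Per-set replicate mean and SD plus a Welch two-sample t test for the
#' named end-point metric.
#'
#' @param set1_runs,set2_runs Lists of [abm_run()] replicates (>= 3 each),
#'   or tibbles of precomputed [tumor_shape_metrics()] rows.
#' @param metric Metric column name.
#' @param labels Length-2 labels for the two sets.
#' @return A list of class `metric_comparison`: `summary` tibble, `t`, `df`,
#'   `p_value`, `metric`.
#' @export
compare_parameter_sets <- function(set1_runs, set2_runs,
                                   metric = "compactness",
                                   labels = c("set1", "set2")) {
  vals <- lapply(list(set1_runs, set2_runs), function(runs) {
    if (is.data.frame(runs)) {
      runs[[metric]]
    } else {
      vapply(runs, function(r) tumor_shape_metrics(r)[[metric]], 1)
    }
  })
  check_that(all(lengths(vals) >= 3), "need >= 3 replicates per set")
  check_that(sd(vals[[1]]) > 0 || sd(vals[[2]]) > 0,
             "zero variance in both sets: degenerate test")
  tt <- t.test(vals[[1]], vals[[2]])
  structure(
    list(summary = tibble::tibble(
      set = labels, n = lengths(vals),
      mean = vapply(vals, mean, 1), sd = vapply(vals, sd, 1)),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, metric = metric, values = vals),
    class = "metric_comparison"
  )
}

#' @export
print.metric_comparison <- function(x, ...) {
  cat(sprintf("<metric_comparison> %s\n", x$metric))
  print(as.data.frame(x$summary), row.names = FALSE)
  cat(sprintf("Welch t = %.3f (df = %.1f), p = %.4g\n", x$t, x$df,
              x$p_value))
  invisible(x)
}

#' @export
tidy.metric_comparison <- function(x, ...) x$summary

#' @export
glance.metric_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric, t = x$t, df = x$df, p_value = x$p_value)
}
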