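# Internal helpers shared across modules.

# micrometres per coarse (tumor) lattice step
coarse_um <- function(config) config$domain_side * 1000 / config$tumor_lattice_n

# micrometres per fine (vessel) lattice step
fine_um <- function(config) config$domain_side * 1000 / config$vessel_lattice_n

# stopifnot with a readable message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)

is_pos <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x > 0

# Squared Euclidean distances from one point `p` (length-3) to rows of `m`.
dist2_point_rows <- function(p, m) {
  (m[, 1] - p[1])^2 + (m[, 2] - p[2])^2 + (m[, 3] - p[3])^2
}

# Distances from rows of `pts` (n x 3) to the segment [a, b] (all physical
# units). Vectorised point-to-segment distance.
dist_points_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(dist2_point_rows(a, pts)))
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
          (pts[, 3] - a[3]) * ab[3]) / len2
  t <- pmin(1, pmax(0, t))
  dx <- a[1] + t * ab[1] - pts[, 1]
  dy <- a[2] + t * ab[2] - pts[, 2]
  dz <- a[3] + t * ab[3] - pts[, 3]
  sqrt(dx * dx + dy * dy + dz * dz)
}
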