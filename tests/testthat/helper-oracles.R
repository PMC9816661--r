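# Shared fixtures and independent oracles used across the test files.

# Construct a bare ABM state with hand-placed cells/vessels, bypassing
# abm_initialize(), for targeted single-phase tests.
# cells: data frame with x, y, z (0-based) and optional phenotype ("stem"/
# "progenitor"), divs, high_mig, senescent, hypoxic columns.
# mature: list of site matrices (each a straight polyline on the fine
# lattice); oxy_all: TRUE (all sites oxygenated), FALSE (none), or NULL
# (computed from the mature vessels).
make_state <- function(config, cells = NULL, mature_sites = list(),
                       oxy_all = NULL) {
  nx <- config$tumor_lattice_n
  n <- if (is.null(cells)) 0L else nrow(cells)
  col_or <- function(nm, default) {
    if (!is.null(cells) && nm %in% names(cells)) as.integer(cells[[nm]])
    else rep(as.integer(default), n)
  }
  cl <- list(
    x = col_or("x", 0), y = col_or("y", 0), z = col_or("z", 0),
    phenotype = col_or("phenotype", 1),
    divs = col_or("divs", 0),
    high_mig = col_or("high_mig", 0),
    senescent = col_or("senescent", 0),
    hypoxic = col_or("hypoxic", 0)
  )
  mature <- lapply(mature_sites, function(m) {
    m <- matrix(as.integer(m), ncol = 3)
    list(p0 = m[1, ], p1 = m[nrow(m), ], sites = m)
  })
  msites <- if (length(mature) > 0) {
    do.call(rbind, lapply(mature, `[[`, "sites"))
  } else {
    matrix(integer(0), ncol = 3)
  }
  mline <- rep(seq_along(mature),
               vapply(mature, function(v) nrow(v$sites), 1L))
  st <- structure(
    list(config = config, iteration = 0L, cells = cl, mature = mature,
         msites = msites, mline = as.integer(mline),
         chains = smorepars:::empty_chains(),
         csites = list(m = matrix(integer(0), ncol = 3),
                       chain = integer(0)),
         oxy = NULL, cum_divisions = 0L, origin_um = c(0, 0, 0)),
    class = "abm_state"
  )
  st$oxy <- if (isTRUE(oxy_all)) {
    rep(TRUE, nx^3)
  } else if (isFALSE(oxy_all)) {
    rep(FALSE, nx^3)
  } else {
    smorepars:::oxy_mask(msites, config)
  }
  st <- abm_classify_oxygenation(st)
  st
}

# Append a sprout chain to a state by hand.
add_chain <- function(state, sites, parent = 1L, open = TRUE,
                      closed_type = 0L, closed_id = NA_integer_) {
  sites <- matrix(as.integer(sites), ncol = 3)
  ch <- state$chains
  ch$parent <- c(ch$parent, as.integer(parent))
  ch$origin <- rbind(ch$origin, sites[1, , drop = FALSE])
  ch$open <- c(ch$open, open)
  ch$closed_type <- c(ch$closed_type, as.integer(closed_type))
  ch$closed_id <- c(ch$closed_id, as.integer(closed_id))
  ch$perfused <- c(ch$perfused, FALSE)
  ch$tip <- rbind(ch$tip, sites[nrow(sites), , drop = FALSE])
  state$chains <- ch
  id <- length(ch$parent)
  state$csites$m <- rbind(state$csites$m, sites)
  state$csites$chain <- c(state$csites$chain, rep(id, nrow(sites)))
  state
}

# Exhaustive-pairwise oxygenation oracle: hypoxic iff the distance to every
# perfused vessel site exceeds oxygen_radius.
oxy_oracle <- function(state) {
  cfg <- state$config
  sites <- smorepars:::perfused_fine_sites(state)
  fu <- smorepars:::fine_um(cfg)
  sp <- smorepars:::coarse_um(cfg)
  cl <- state$cells
  vapply(seq_along(cl$x), function(i) {
    if (nrow(sites) == 0) return(1L)
    p <- c(cl$x[i], cl$y[i], cl$z[i]) * sp
    d2 <- (sites[, 1] * fu - p[1])^2 + (sites[, 2] * fu - p[2])^2 +
      (sites[, 3] * fu - p[3])^2
    as.integer(sqrt(min(d2)) > cfg$oxygen_radius)
  }, 1L)
}

# Deterministic branching-process enumeration: every non-senescent
# progenitor divides each iteration (unbounded space), parent and daughter
# sharing the incremented division count. Returns per-iteration totals.
enumerate_branching <- function(div_lim, iters) {
  counts <- rep(0, div_lim + 1)  # index d+1 = cells with d divisions used
  counts[1] <- 1
  out <- integer(iters)
  for (t in seq_len(iters)) {
    newc <- rep(0, div_lim + 1)
    for (d in 0:div_lim) {
      n <- counts[d + 1]
      if (n == 0) next
      if (d == div_lim) newc[d + 1] <- newc[d + 1] + n  # senescent persist
      else newc[d + 2] <- newc[d + 2] + 2 * n
    }
    counts <- newc
    out[t] <- sum(counts)
  }
  out
}

# igraph-based perfusion oracle, independent of perfusion_flags(): vertices
# are the merged mature network plus closed chains; a chain is perfused iff
# closed and both attachment objects exist and connect to the mature vertex.
perfusion_oracle <- function(parent_type, parent_id, closed,
                             closed_to_type, closed_to_id) {
  k <- length(closed)
  closed_idx <- which(closed)
  vs <- c("M", paste0("C", closed_idx))
  vert <- function(type, id) {
    if (is.na(type)) return(NA_character_)
    if (type == "mature") return("M")
    v <- paste0("C", id)
    if (v %in% vs) v else NA_character_
  }
  edges <- character(0)
  for (i in closed_idx) {
    for (o in c(vert(parent_type[i], parent_id[i]),
                vert(closed_to_type[i], closed_to_id[i]))) {
      if (!is.na(o)) edges <- c(edges, paste0("C", i), o)
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(vs)
  if (length(edges) > 0) g <- g + igraph::edges(edges)
  comp <- igraph::components(g)$membership
  reach <- names(comp)[comp == comp[["M"]]]
  out <- logical(k)
  for (i in closed_idx) {
    a1 <- vert(parent_type[i], parent_id[i])
    a2 <- vert(closed_to_type[i], closed_to_id[i])
    out[i] <- !is.na(a1) && !is.na(a2) && a1 %in% reach && a2 %in% reach
  }
  out
}

# Independent scalar bilinear interpolation for the surface oracles.
bilinear_oracle <- function(xs, ys, zmat, x, y) {
  i <- findInterval(x, xs, rightmost.closed = TRUE)
  j <- findInterval(y, ys, rightmost.closed = TRUE)
  i <- min(max(i, 1), length(xs) - 1)
  j <- min(max(j, 1), length(ys) - 1)
  tx <- (x - xs[i]) / (xs[i + 1] - xs[i])
  ty <- (y - ys[j]) / (ys[j + 1] - ys[j])
  (1 - tx) * (1 - ty) * zmat[i, j] + tx * (1 - ty) * zmat[i + 1, j] +
    (1 - tx) * ty * zmat[i, j + 1] + tx * ty * zmat[i + 1, j + 1]
}

# Random complete node grid for surface tests.
random_nodes <- function(param = "beta", xs = c(0.05, 0.125, 0.245),
                         ys = c(8, 12, 15)) {
  g <- expand.grid(p_div = xs, div_lim = ys)
  mle <- runif(nrow(g), 0.1, 1)
  tibble::tibble(
    p_div = g$p_div, div_lim = g$div_lim, param = param,
    lower = mle * runif(nrow(g), 0.5, 0.95), mle = mle,
    upper = mle * runif(nrow(g), 1.05, 2)
  )
}

small_abm_config <- function(...) {
  abm_config(n_iterations = 10, ...)
}
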