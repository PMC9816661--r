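# Morphology metrics: distances, box counting, component filtering,
# enclosing-surface geometry, compactness, and replicate comparison.

test_that("farthest-cell distance follows the Euclidean definition", {
  expect_equal(farthest_cell_distance(cbind(0, 0, 0), c(0, 0, 0)), 0)
  # offsets (3,4,0) and (1,1,1) at 20 um spacing: 5 sites x 20 um = 100 um
  cells <- rbind(c(3, 4, 0), c(1, 1, 1))
  expect_equal(farthest_cell_distance(cells, c(0, 0, 0), spacing = 20), 100)
  # adding cells never decreases the maximum
  more <- rbind(cells, c(2, 2, 2))
  expect_gte(farthest_cell_distance(more, c(0, 0, 0)),
             farthest_cell_distance(cells, c(0, 0, 0)))
  expect_error(farthest_cell_distance(cells[0, , drop = FALSE]), "empty")
})

test_that("box counting recovers known dimensions", {
  line <- cbind(0:511, 0L, 0L)
  d1 <- box_count_dimension(line)
  expect_gte(d1, 0.9)
  expect_lte(d1, 1.1)
  cube <- as.matrix(expand.grid(0:63, 0:63, 0:63))
  d3 <- box_count_dimension(cube)
  expect_gte(d3, 2.9)
  expect_lte(d3, 3.0 + 1e-9)
  expect_error(box_count_dimension(cbind(1, 1, 1)), "at least")
})

test_that("box counting is invariant under rigid translation", {
  set.seed(12)
  pts <- unique(cbind(sample(0:100, 400, TRUE), sample(0:100, 400, TRUE),
                      sample(0:30, 400, TRUE)))
  d0 <- box_count_dimension(pts)
  d1 <- box_count_dimension(sweep(pts, 2, c(-57, 13, 211), `-`))
  expect_equal(as.numeric(d0), as.numeric(d1), tolerance = 1e-12)
})

test_that("component filtering removes only sub-threshold satellites", {
  main <- as.matrix(expand.grid(0:5, 0:5, 0:5))        # 216 voxels
  sat49 <- as.matrix(expand.grid(20:26, 20:26, 20L))[1:49, ]
  sat50 <- as.matrix(expand.grid(40:47, 40:46, 40L))[1:50, ]
  all_pts <- rbind(main, sat49, sat50)
  kept <- filter_small_components(all_pts, threshold = 50)
  expect_equal(nrow(kept), 216 + 50)                    # 49er removed
  expect_true(all(kept[, 1] <= 5 | kept[, 1] >= 40))
  # exactly-at-threshold component is retained (strict <)
  expect_true(any(kept[, 1] >= 40))
  # idempotence
  expect_equal(nrow(filter_small_components(kept, threshold = 50)),
               nrow(kept))
})

test_that("the enclosing surface recovers block geometry and excludes satellites", {
  block <- as.matrix(expand.grid(0:9, 0:9, 0:9))
  sv <- tumor_surface_volume(block, component_threshold = 50, spacing = 20)
  expect_lt(abs(sv$volume - 200^3) / 200^3, 0.15)
  expect_lt(abs(sv$surface_area - 6 * 200^2) / (6 * 200^2), 0.15)
  sat <- as.matrix(expand.grid(30:36, 30:36, 30L))[1:49, ]
  sv2 <- tumor_surface_volume(rbind(block, sat), component_threshold = 50,
                              spacing = 20)
  expect_equal(sv2$volume, sv$volume)
  expect_equal(sv2$surface_area, sv$surface_area)
  expect_error(tumor_surface_volume(sat, component_threshold = 50), "survive")
})

test_that("compactness is exactly 1 for an analytic sphere and (36pi)^(1/6)/sqrt(6) for a cube", {
  r <- 7.3
  expect_equal(compactness(4 * pi * r^2, 4 / 3 * pi * r^3), 1,
               tolerance = 1e-12)
  s <- 3.1
  cube_comp <- compactness(6 * s^2, s^3)
  expect_equal(cube_comp, (36 * pi)^(1 / 6) / sqrt(6), tolerance = 1e-12)
  expect_equal(round(cube_comp, 3), 0.898)
  # scale invariance of the dimensionless form
  expect_equal(compactness(6 * (10 * s)^2, (10 * s)^3), cube_comp)
  # the literal (non-dimensionless) variant scales with size
  expect_false(isTRUE(all.equal(
    compactness(6 * s^2, s^3, literal = TRUE),
    compactness(6 * (10 * s)^2, (10 * s)^3, literal = TRUE))))
  expect_error(compactness(0, 1), "> 0")
})

test_that("no tested voxel shape exceeds sphere compactness", {
  set.seed(5)
  shapes <- list(
    as.matrix(expand.grid(0:9, 0:9, 0:9)),
    as.matrix(expand.grid(0:19, 0:4, 0:2)),
    {
      g <- as.matrix(expand.grid(-12:12, -12:12, -12:12))
      g[rowSums(g^2) <= 144, ]
    }
  )
  for (s in shapes) {
    sv <- tumor_surface_volume(s, component_threshold = 1, spacing = 20)
    expect_lte(compactness(sv$surface_area, sv$volume), 1 + 1e-6)
  }
})

test_that("Welch comparison matches the hand-computed statistic", {
  x <- c(1.0, 1.2, 0.9)
  y <- c(2.1, 2.0, 2.3)
  cmp <- compare_parameter_sets(
    tibble::tibble(compactness = x), tibble::tibble(compactness = y),
    metric = "compactness")
  sp <- sqrt(var(x) / 3 + var(y) / 3)
  t_hand <- (mean(x) - mean(y)) / sp
  df_hand <- sp^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(cmp$t, t_hand, tolerance = 1e-12)
  expect_equal(cmp$df, df_hand, tolerance = 1e-12)
  expect_equal(cmp$p_value, 2 * pt(-abs(t_hand), df_hand),
               tolerance = 1e-12)
})

test_that("identical sets give t = 0 and separated sets give small p", {
  a <- tibble::tibble(compactness = c(1, 2, 3))
  same <- compare_parameter_sets(a, a, metric = "compactness")
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  b1 <- tibble::tibble(compactness = c(1, 1.001, 0.999))
  b2 <- tibble::tibble(compactness = c(2, 2.001, 1.999))
  sep <- compare_parameter_sets(b1, b2, metric = "compactness")
  expect_lt(sep$p_value, 0.01)
  z <- tibble::tibble(compactness = c(1, 1, 1))
  expect_error(compare_parameter_sets(z, z, metric = "compactness"),
               "degenerate")
})

test_that("shape metrics of a simulated tumor are finite and coherent", {
  run <- abm_run(abm_config(p_div = 0.245, div_lim = 8, n_iterations = 60),
                 seed = 4)
  m <- tumor_shape_metrics(run)
  expect_true(all(is.finite(unlist(m))))
  expect_gt(m$compactness, 0)
  expect_lte(m$compactness, 1 + 1e-6)
  expect_equal(m$sa_to_vol, m$surface_area_um2 / m$volume_um3)
  expect_gt(m$farthest_distance_um, 0)
})
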