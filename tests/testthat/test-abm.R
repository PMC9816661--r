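# Tumor-module behaviour: initialization, oxygenation, divisions,
# migrations, stepping, and whole-run properties.

test_that("initialization packs the tumor into the corner with the right census", {
  set.seed(1)
  st <- abm_initialize(abm_config())
  cl <- st$cells
  expect_equal(length(cl$x), 100L)
  expect_equal(sum(cl$phenotype == 0L), 20L)
  expect_equal(sum(cl$phenotype == 1L), 80L)
  expect_equal(length(st$mature), 8L)
  # all mature vessels perfused and on the boundary faces
  expect_true(all(apply(st$msites, 1, function(p) any(p == 0))))
  # 100 cells in the 5 x 5 x 4 corner block, one per site
  expect_true(all(cl$x <= 4 & cl$y <= 4 & cl$z <= 3))
  expect_equal(anyDuplicated(cbind(cl$x, cl$y, cl$z)), 0L)
  expect_equal(st$iteration, 0L)
})

test_that("empty-tumor initialization is valid and capacity overflow errors", {
  set.seed(1)
  st <- abm_initialize(abm_config(n_stem_init = 0, n_prog_init = 0))
  expect_equal(length(st$cells$x), 0L)
  expect_error(
    abm_initialize(abm_config(tumor_lattice_n = 5, vessel_lattice_n = 50,
                              n_stem_init = 100, n_prog_init = 100)),
    "capacity"
  )
})

test_that("initialization is deterministic under a fixed seed", {
  cfg <- abm_config()
  set.seed(7)
  a <- abm_initialize(cfg)
  set.seed(7)
  b <- abm_initialize(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$oxy, b$oxy)
})

test_that("oxygenation classification matches the exhaustive distance oracle", {
  cfg <- abm_config()
  # one perfused vessel along x at y = 50, z = 0 (fine units)
  line <- cbind(0:499, 50L, 0L)
  # cells straddling the 100 um oxygen radius from the vessel line:
  # perpendicular (y,z) distances from (100,0) um at 20 um spacing
  cells <- data.frame(x = 10, y = c(5, 9, 10, 12), z = c(0, 2, 0, 3))
  st <- make_state(cfg, cells, mature_sites = list(line))
  st <- abm_classify_oxygenation(st, recompute = TRUE)
  expect_equal(st$cells$hypoxic, oxy_oracle(st))
  # zero distance: cell coincident with the vessel
  st2 <- make_state(cfg, data.frame(x = 10, y = 5, z = 0),
                    mature_sites = list(line))
  expect_equal(st2$cells$hypoxic, 0L)
  # no perfused vessels at all: everything hypoxic
  st3 <- make_state(cfg, cells)
  expect_true(all(st3$cells$hypoxic == 1L))
})

test_that("oxygenation of a full initial state matches the oracle", {
  set.seed(3)
  st <- abm_initialize(abm_config())
  expect_equal(st$cells$hypoxic, oxy_oracle(st))
})

test_that("null dynamics: zero division probabilities leave the census unchanged", {
  cfg <- abm_config(p_div = 0, stem_div_prob = 0)
  st <- make_state(cfg, data.frame(x = c(5, 7), y = c(5, 7), z = c(5, 7),
                                   phenotype = c(0, 1)), oxy_all = TRUE)
  set.seed(1)
  st2 <- abm_attempt_divisions(st)
  expect_equal(length(st2$cells$x), 2L)
  expect_equal(st2$cum_divisions, 0L)
})

test_that("deterministic branching matches the enumeration oracle", {
  cfg <- abm_config(p_div = 1, hypoxic_div_factor = 1, div_lim = 3,
                    stem_div_prob = 0, senescent_death_prob = 0)
  st <- make_state(cfg, data.frame(x = 25, y = 25, z = 25, phenotype = 1),
                   oxy_all = TRUE)
  expected <- enumerate_branching(div_lim = 3, iters = 4)
  set.seed(42)
  for (t in 1:4) {
    st <- abm_attempt_divisions(st)
    expect_equal(length(st$cells$x), expected[t])
  }
  expect_true(all(st$cells$divs == 3L))
  expect_true(all(st$cells$senescent == 1L))
})

test_that("forced symmetric stem division yields two stems", {
  cfg <- abm_config(stem_div_prob = 1, stem_symmetric_prob = 1, p_div = 0)
  st <- make_state(cfg, data.frame(x = 10, y = 10, z = 10, phenotype = 0),
                   oxy_all = TRUE)
  set.seed(5)
  st <- abm_attempt_divisions(st)
  expect_equal(length(st$cells$x), 2L)
  expect_true(all(st$cells$phenotype == 0L))
})

test_that("migration realises the closed-form expected step count", {
  # 0.83 um/h for 6 h on a 20 um lattice: 0.249 expected steps/iteration;
  # a single interior cell moves iff its Bernoulli step fires
  cfg <- abm_config(p_div = 0, stem_div_prob = 0, low_migration_rate = 0.83,
                    p_high_migratory_daughter = 0)
  st <- make_state(cfg, data.frame(x = 25, y = 25, z = 25, high_mig = 0),
                   oxy_all = TRUE)
  set.seed(11)
  n <- 10000
  moved <- logical(n)
  for (i in seq_len(n)) {
    old <- c(st$cells$x, st$cells$y, st$cells$z)
    st <- abm_attempt_migrations(st)
    moved[i] <- !identical(old, c(st$cells$x, st$cells$y, st$cells$z))
  }
  e <- 0.83 * 6 / 20
  se <- sqrt(e * (1 - e) / n)
  expect_lt(abs(mean(moved) - e), 3 * se)
})

test_that("fully blocked and rate-zero cells stay put", {
  cfg <- abm_config(p_div = 0, stem_div_prob = 0,
                    high_migration_rate = 8.3)
  # center cell with all 26 neighbors occupied, everyone high-migratory
  nb <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  cells <- data.frame(x = 25 + nb$dx, y = 25 + nb$dy, z = 25 + nb$dz,
                      high_mig = 1)
  st <- make_state(cfg, cells, oxy_all = TRUE)
  set.seed(2)
  st2 <- abm_attempt_migrations(st)
  i <- which(st2$cells$x == 25 & st2$cells$y == 25 & st2$cells$z == 25)
  expect_length(i, 1L)
  # zero rates: nobody moves at all
  cfg0 <- abm_config(p_div = 0, stem_div_prob = 0, high_migration_rate = 0,
                     low_migration_rate = 0)
  st0 <- make_state(cfg0, data.frame(x = 10, y = 10, z = 10), oxy_all = TRUE)
  st0b <- abm_attempt_migrations(st0)
  expect_identical(st0$cells, st0b$cells)
})

test_that("stepping an empty tumor stays empty with no sprouting", {
  cfg <- abm_config(n_stem_init = 0, n_prog_init = 0, n_iterations = 3)
  set.seed(1)
  st <- abm_initialize(cfg)
  for (i in 1:3) st <- abm_step(st)
  expect_equal(length(st$cells$x), 0L)
  expect_equal(length(st$chains$parent), 0L)
})

test_that("state invariants and the division ledger hold across steps", {
  cfg <- abm_config(p_div = 0.245, div_lim = 8)
  set.seed(9)
  st <- abm_initialize(cfg)
  nx <- cfg$tumor_lattice_n
  for (i in 1:25) {
    n_before <- length(st$cells$x)
    cum_before <- st$cum_divisions
    st <- abm_step(st)
    cl <- st$cells
    # one cell per site, in bounds
    expect_equal(anyDuplicated(cbind(cl$x, cl$y, cl$z)), 0L)
    expect_true(all(cl$x >= 0 & cl$x < nx & cl$y >= 0 & cl$y < nx &
                      cl$z >= 0 & cl$z < nx))
    # ledger: N(t+1) = N(t) + divisions - deaths
    expect_equal(length(cl$x),
                 n_before + st$last_divisions - st$last_deaths)
    expect_equal(st$cum_divisions - cum_before, st$last_divisions)
    # senescence cap
    expect_true(all(cl$divs <= cfg$div_lim))
    expect_true(all(cl$senescent[cl$divs == cfg$div_lim & cl$phenotype == 1L]
                    == 1L))
  }
})

test_that("runs are reproducible and reported per iteration", {
  cfg <- abm_config(n_iterations = 15)
  a <- abm_run(cfg, seed = 123)
  b <- abm_run(cfg, seed = 123)
  expect_identical(a$series, b$series)
  expect_identical(a$cells, b$cells)
  expect_identical(a$vessels, b$vessels)
  expect_equal(nrow(a$series), 15L)
  expect_equal(a$series$time_hours, (1:15) * 6)
  expect_true(all(a$series$n_hypoxic <= a$series$n_cells))
  expect_true(all(a$series$n_stem <= a$series$n_cells))
  expect_true(all(diff(a$series$cum_divisions) >= 0))
})

test_that("final cell count responds monotonically to proliferation parameters", {
  lo <- abm_config(p_div = 0.05, div_lim = 8, n_iterations = 40)
  hi <- abm_config(p_div = 0.245, div_lim = 15, n_iterations = 40)
  n_lo <- vapply(abm_run_replicates(lo, reps = 3, seed = 100),
                 function(r) tail(r$series$n_cells, 1), 1L)
  n_hi <- vapply(abm_run_replicates(hi, reps = 3, seed = 100),
                 function(r) tail(r$series$n_cells, 1), 1L)
  expect_gt(mean(n_hi), mean(n_lo))
})

test_that("tidiers and autoplot work on runs", {
  run <- abm_run(abm_config(n_iterations = 5), seed = 1)
  expect_s3_class(tidy(run), "tbl_df")
  expect_equal(nrow(glance(run)), 1L)
  expect_s3_class(autoplot(run), "ggplot")
})
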