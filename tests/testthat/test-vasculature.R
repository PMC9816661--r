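# Angiogenesis: sprouting probabilities, tip chemotaxis, anastomosis, and
# perfusion semantics.

test_that("no hypoxic cells means no sprouts, ever", {
  cfg <- abm_config()
  line <- cbind(0:499, 50L, 0L)
  st <- make_state(cfg, data.frame(x = 10, y = 10, z = 10),
                   mature_sites = list(line), oxy_all = TRUE)
  set.seed(1)
  for (i in 1:5) st <- vasc_branch(st)
  expect_equal(length(st$chains$parent), 0L)
})

test_that("branching frequency matches the linear proximity law", {
  cfg <- abm_config()
  # single-site mature vessel at fine (100, 100, 100) = (200, 200, 200) um
  seg <- matrix(c(100L, 100L, 100L), ncol = 3)
  set.seed(21)
  freqs <- sapply(list(c(10, 10, 10),    # d = 0 um -> p = 0.2
                       c(15, 10, 10),    # d = 100 um -> p = 0.1
                       c(20, 10, 10)),   # d = 200 um = vegf_radius -> p = 0
                  function(pos) {
    st <- make_state(cfg,
                     data.frame(x = pos[1], y = pos[2], z = pos[3]),
                     mature_sites = list(seg), oxy_all = FALSE)
    n <- 3000
    sprouted <- integer(n)
    for (i in seq_len(n)) {
      st2 <- vasc_branch(st)
      sprouted[i] <- length(st2$chains$parent)
    }
    mean(sprouted)
  })
  for (k in seq_along(freqs)) {
    p <- c(0.2, 0.1, 0)[k]
    se <- sqrt(max(p * (1 - p), 1e-9) / 3000)
    expect_lt(abs(freqs[k] - p), 3 * se + 1e-12)
  }
})

test_that("tips advance axis-aligned toward a lone target and stall without cells", {
  cfg <- abm_config()
  seg <- matrix(c(50L, 100L, 100L), ncol = 3)
  # cancer cell due +x of the tip (fine coords of cell = 10 * coarse)
  st <- make_state(cfg, data.frame(x = 40, y = 10, z = 10),
                   mature_sites = list(seg), oxy_all = TRUE)
  st <- add_chain(st, seg, parent = 1L)
  st2 <- vasc_migrate_tips(st)
  expect_gt(st2$chains$tip[1, 1], 50)
  expect_equal(st2$chains$tip[1, 2], 100)
  expect_equal(st2$chains$tip[1, 3], 100)
  # tip advances tip_speed / fine spacing = 10 sites per iteration
  expect_equal(st2$chains$tip[1, 1], 60)

  st_empty <- make_state(cfg, mature_sites = list(seg))
  st_empty <- add_chain(st_empty, seg, parent = 1L)
  st3 <- vasc_migrate_tips(st_empty)
  expect_equal(st3$chains$tip, st_empty$chains$tip)
})

test_that("equidistant targets resolve identically across repeat runs", {
  cfg <- abm_config()
  seg <- matrix(c(100L, 100L, 100L), ncol = 3)
  cells <- data.frame(x = c(5, 15), y = 10, z = 10)  # symmetric about tip
  st <- make_state(cfg, cells, mature_sites = list(seg), oxy_all = TRUE)
  st <- add_chain(st, seg, parent = 1L)
  a <- vasc_migrate_tips(st)
  b <- vasc_migrate_tips(st)
  expect_identical(a$chains$tip, b$chains$tip)
  # lexicographic tie-break picks the lower-coordinate cell (-x direction)
  expect_lt(a$chains$tip[1, 1], 100)
})

test_that("coincident tips fuse mutually; distant tips do not", {
  cfg <- abm_config()
  line1 <- cbind(0:499, 50L, 0L)
  line2 <- cbind(0:499, 0L, 50L)
  st <- make_state(cfg, mature_sites = list(line1, line2))
  st <- add_chain(st, rbind(c(250L, 50L, 0L), c(250L, 80L, 30L)), parent = 1L)
  st <- add_chain(st, rbind(c(250L, 0L, 50L), c(250L, 80L, 30L)), parent = 2L)
  st2 <- vasc_anastomose(st)
  expect_false(any(st2$chains$open))
  expect_true(all(st2$chains$closed_type == 2L))  # fused chain-to-chain

  st3 <- make_state(cfg, mature_sites = list(line1, line2))
  st3 <- add_chain(st3, rbind(c(250L, 50L, 0L), c(250L, 100L, 100L)),
                   parent = 1L)
  st3 <- add_chain(st3, rbind(c(250L, 0L, 50L), c(250L, 300L, 300L)),
                   parent = 2L)
  st4 <- vasc_anastomose(st3)
  expect_true(all(st4$chains$open))
})

test_that("a tip near a foreign stalk closes onto that chain", {
  cfg <- abm_config()
  line <- cbind(0:499, 50L, 0L)
  st <- make_state(cfg, mature_sites = list(line))
  # chain 1: a long stalk heading into the domain
  stalk <- cbind(100L, 50L + 10L * (0:20), 0L + 5L * (0:20))
  st <- add_chain(st, stalk, parent = 1L)
  # chain 2: tip within one fine site of chain 1's stalk interior
  st <- add_chain(st, rbind(c(300L, 50L, 0L), c(101L, 150L, 50L)),
                  parent = 1L)
  st2 <- vasc_anastomose(st)
  expect_false(st2$chains$open[2])
  expect_equal(st2$chains$closed_type[2], 2L)
  expect_equal(st2$chains$closed_id[2], 1L)
})

test_that("fresh sprouts do not instantly fuse back at their branch point", {
  cfg <- abm_config()
  line <- cbind(0:499, 50L, 0L)
  st <- make_state(cfg, mature_sites = list(line))
  st <- add_chain(st, matrix(c(250L, 50L, 0L), ncol = 3), parent = 1L)
  st2 <- vasc_anastomose(st)
  expect_true(st2$chains$open[1])
})

test_that("perfusion requires completed loops anchored to the mature network", {
  cfg <- abm_config()
  line <- cbind(0:499, 50L, 0L)
  st <- make_state(cfg, mature_sites = list(line))
  st <- add_chain(st, rbind(c(100L, 50L, 0L), c(100L, 60L, 10L)),
                  parent = 1L)                                   # open
  st <- add_chain(st, rbind(c(200L, 50L, 0L), c(220L, 50L, 0L)),
                  parent = 1L, open = FALSE, closed_type = 1L,
                  closed_id = 1L)                                # to mature
  st <- add_chain(st, rbind(c(300L, 50L, 0L), c(210L, 51L, 0L)),
                  parent = 1L, open = FALSE, closed_type = 2L,
                  closed_id = 2L)                                # to chain 2
  st <- add_chain(st, rbind(c(400L, 50L, 0L), c(100L, 59L, 9L)),
                  parent = 1L, open = FALSE, closed_type = 2L,
                  closed_id = 1L)                                # to open ch.
  st2 <- update_perfusion(st)
  expect_equal(st2$chains$perfused, c(FALSE, TRUE, TRUE, FALSE))
  # perfusion monotone: re-updating never removes flags
  st3 <- update_perfusion(st2)
  expect_equal(st3$chains$perfused, st2$chains$perfused)
})

test_that("perfusion flags equal the independent graph oracle on random networks", {
  set.seed(31)
  for (rep in 1:25) {
    k <- sample(3:30, 1)
    parent_type <- sample(c("mature", "chain"), k, replace = TRUE,
                          prob = c(0.8, 0.2))
    parent_id <- ifelse(parent_type == "chain",
                        sample.int(k, k, replace = TRUE), 1L)
    closed <- runif(k) < 0.7
    closed_to_type <- ifelse(closed,
                             sample(c("mature", "chain"), k, replace = TRUE),
                             NA_character_)
    closed_to_id <- ifelse(!is.na(closed_to_type) & closed_to_type == "chain",
                           sample.int(k, k, replace = TRUE), 1L)
    closed_to_id[is.na(closed_to_type)] <- NA_integer_
    got <- perfusion_flags(parent_type, parent_id, closed, closed_to_type,
                           closed_to_id)
    want <- perfusion_oracle(parent_type, parent_id, closed, closed_to_type,
                             closed_to_id)
    expect_equal(got, want)
  }
})

test_that("vessel sites only accumulate and activity ceases without stimulus", {
  cfg <- abm_config(p_div = 0.245, div_lim = 8)
  set.seed(13)
  st <- abm_initialize(cfg)
  n_prev <- nrow(st$csites$m) + nrow(st$msites)
  for (i in 1:15) {
    st <- abm_step(st)
    n_now <- nrow(st$csites$m) + nrow(st$msites)
    expect_gte(n_now, n_prev)
    n_prev <- n_now
    # no perfused chain is open
    expect_false(any(st$chains$perfused & st$chains$open))
  }
  # no hypoxia and no open tips: the vasculature freezes
  st$cells$hypoxic <- rep(0L, length(st$cells$x))
  st$oxy <- rep(TRUE, cfg$tumor_lattice_n^3)
  st$chains$open <- rep(FALSE, length(st$chains$open))
  before <- nrow(st$csites$m)
  st2 <- vasc_branch(vasc_migrate_tips(st))
  expect_equal(nrow(st2$csites$m), before)
  expect_equal(length(st2$chains$parent), length(st$chains$parent))
})
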