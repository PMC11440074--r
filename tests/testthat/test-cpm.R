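test_that("target assignment: in-band cells keep their own measurements", {
  ft <- data.frame(cell_id = 1:5,
                   volume = c(100, 120, 90, 110, 105),
                   surface = c(60, 70, 55, 65, 62))
  class(ft) <- c("morphology_table", "data.frame")
  # every volume is inside [0.15*mean, mean + 2*sd]
  expect_true(all(ft$volume >= 0.15 * mean(ft$volume) &
                    ft$volume <= mean(ft$volume) + 2 * sd(ft$volume)))
  tg <- assign_targets(ft, seed = 5)
  expect_false(any(tg$resampled))
  expect_equal(tg$target_volume, ft$volume)
  expect_equal(tg$target_surface, ft$surface)
})

test_that("out-of-band cells receive jointly sampled donor (V, A) pairs", {
  ft <- data.frame(
    cell_id = 1:8,
    volume = c(100, 110, 95, 105, 98, 102, 2, 400),
    surface = c(60, 66, 57, 63, 59, 61, 3, 150)
  )
  class(ft) <- c("morphology_table", "data.frame")
  mu <- mean(ft$volume)
  sdv <- sd(ft$volume)
  expect_true(ft$volume[7] < 0.15 * mu)       # constructed small outlier
  expect_true(ft$volume[8] > mu + 2 * sdv)    # constructed large outlier
  tg <- assign_targets(ft, seed = 3)
  expect_identical(which(tg$resampled), c(7L, 8L))
  expect_equal(tg$target_volume[1:6], ft$volume[1:6])
  in_band <- ft[1:6, ]
  for (i in 7:8) {
    j <- match(tg$target_volume[i], in_band$volume)
    expect_false(is.na(j))
    expect_equal(tg$target_surface[i], in_band$surface[j]) # joint pair
  }
  # deterministic under the seed
  expect_identical(assign_targets(ft, seed = 3), tg)
})

test_that("a single cell is its own band; all-out-of-band errors", {
  ft <- data.frame(cell_id = 1L, volume = 50, surface = 30)
  tg <- assign_targets(ft)
  expect_false(tg$resampled)
  expect_equal(tg$target_volume, 50)
})

test_that("init_state builds the wall shell and exact bookkeeping", {
  v <- random_cell_volume(c(12, 12, 12), n_cells = 4, seed = 2)
  st <- init_state(v, identity_targets(v), model_params())
  d <- dim(st$lattice)
  # wall claims exactly the boundary voxels
  expect_true(all(st$lattice[c(1, d[1]), , ] == st$wall_id))
  expect_true(all(st$lattice[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] !=
                    st$wall_id))
  cells <- st$cells[st$cells$celltype == "Cell", ]
  orc_v <- table(v$lattice[v$lattice > 0])
  orc_a <- oracle_face_area(st$lattice)
  expect_equal(cells$volume,
               unname(as.numeric(orc_v[as.character(cells$cell_id)])))
  expect_equal(cells$surface,
               unname(as.numeric(orc_a[as.character(cells$cell_id)])))
  expect_equal(st$mcs, 0L)
  expect_equal(sum(cells$volume), sum(v$lattice > 0))
})

test_that("init_state rejects cells on the boundary and handles empty interiors", {
  v <- make_vol(c(6, 6, 6))
  v$lattice[1, 3, 3] <- 2L
  expect_error(init_state(v, data.frame(cell_id = 2L, target_volume = 1,
                                        target_surface = 6)),
               "wall shell")
  st <- init_state(make_vol(c(5, 5, 5)))
  expect_identical(st$cells$celltype, "Wall")
})

test_that("hamiltonian matches closed forms on constructed states", {
  v <- make_vol(c(8, 8, 8))
  v$lattice[3:4, 3:4, 3:4] <- 1L   # 2x2x2 cube, 24 medium-contact faces
  tg <- identity_targets(v)
  st <- init_state(v, tg)

  p0 <- model_params(lambda_V = 0, lambda_A = 0, J_cc = 0, J_cm = 0, J_cw = 0)
  expect_equal(hamiltonian(st, p0), 0)

  p1 <- model_params(lambda_V = 3, lambda_A = 2, J_cc = 0, J_cm = 7, J_cw = 0)
  expect_equal(hamiltonian(st, p1), 7 * 24)  # at targets: only contact term

  # off-target penalties are quadratic
  st2 <- st
  st2$cells$target_volume[1] <- st2$cells$volume[1] + 5
  st2$cells$target_surface[1] <- st2$cells$surface[1] - 2
  expect_equal(hamiltonian(st2, p1), 3 * 25 + 2 * 4 + 7 * 24)

  # doubling J_cc doubles the cell-cell term only
  v2 <- make_vol(c(10, 8, 8))
  v2$lattice[3:4, 3:4, 3:4] <- 1L
  v2$lattice[5:6, 3:4, 3:4] <- 2L  # shares a 2x2 interface: 4 faces
  stw <- init_state(v2, identity_targets(v2))
  pa <- model_params(lambda_V = 0, lambda_A = 0, J_cc = 3, J_cm = 5, J_cw = 0)
  pb <- model_params(lambda_V = 0, lambda_A = 0, J_cc = 6, J_cm = 5, J_cw = 0)
  expect_equal(hamiltonian(stw, pb) - hamiltonian(stw, pa), 3 * 4)
})

test_that("incremental delta_H equals the full-Hamiltonian difference", {
  n_checked <- 0L
  for (seed in 1:3) {
    v <- random_cell_volume(c(10, 10, 10), n_cells = 3, seed = seed)
    tg <- identity_targets(v)
    # push some targets off their measurements so both penalty terms engage
    tg$target_volume <- tg$target_volume + seq_len(nrow(tg))
    tg$target_surface <- tg$target_surface - seq_len(nrow(tg))
    params <- model_params(lambda_V = 1.5, lambda_A = 0.7, J_cc = 2,
                           J_cm = 11, J_cw = 100,
                           contact_neighbor_order = (seed - 1L) %% 3L + 1L)
    st <- init_state(v, tg, params)
    h0 <- hamiltonian(st, params)
    d <- dim(st$lattice)
    set.seed(100 + seed)
    for (k in 1:60) {
      site <- c(sample(2:(d[1] - 1), 1), sample(2:(d[2] - 1), 1),
                sample(2:(d[3] - 1), 1))
      cur <- st$lattice[site[1], site[2], site[3]]
      nbrs <- st$lattice[site[1] + (-1:1), site[2] + (-1:1), site[3] + (-1:1)]
      cand <- setdiff(unique(as.integer(nbrs)), c(cur, st$wall_id))
      if (length(cand) == 0L) next
      cand <- cand[sample.int(length(cand), 1L)]
      dh <- delta_H(st, params, site, cand)
      st_after <- st
      st_after$lattice[site[1], site[2], site[3]] <- cand
      expect_equal(dh, hamiltonian(st_after, params) - h0,
                   tolerance = 1e-9)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 100)
})

test_that("delta_H enforces its preconditions", {
  v <- random_cell_volume(c(8, 8, 8), n_cells = 2, seed = 4)
  st <- init_state(v, identity_targets(v))
  p <- model_params()
  expect_error(delta_H(st, p, c(1, 4, 4), 0L), "interior")
  idx <- which(array(st$lattice == 1L, dim(st$lattice)), arr.ind = TRUE)[1, ]
  expect_error(delta_H(st, p, idx, 1L), "candidate ID equals")
  expect_error(delta_H(st, p, idx, st$wall_id), "wall")
})

test_that("bookkeeping stays exact over many MCS and volume sums are conserved", {
  v <- generate_spheroid(spheroid_spec(n_cells = 15, radius = 9, seed = 3))
  st <- init_state(v, params = model_params())
  p <- model_params(temperature = 15, lambda_V = 2, lambda_A = 0.5)
  set.seed(77)
  st <- mcs_step(st, p, n = 30)
  cells <- st$cells[st$cells$celltype == "Cell", ]
  rec_v <- tabulate(st$lattice, nbins = st$wall_id)
  orc_a <- oracle_face_area(st$lattice)
  expect_identical(cells$volume, as.numeric(rec_v[cells$cell_id]))
  got_a <- as.numeric(orc_a[as.character(cells$cell_id)])
  got_a[is.na(got_a)] <- 0
  expect_identical(cells$surface, got_a)
  expect_equal(sum(cells$volume),
               sum(st$lattice > 0L & st$lattice != st$wall_id))
  # running energy equals full recomputation
  expect_equal(attr(st, "h_trace")[31], hamiltonian(st, p),
               tolerance = 1e-9)
})

test_that("wall shell is immutable under dynamics", {
  v <- generate_spheroid(spheroid_spec(n_cells = 8, radius = 7, seed = 8))
  st <- init_state(v, params = model_params())
  wall_before <- which(st$lattice == st$wall_id)
  set.seed(5)
  st <- mcs_step(st, model_params(temperature = 50, lambda_V = 0.001), n = 20)
  expect_identical(which(st$lattice == st$wall_id), wall_before)
})

test_that("Metropolis acceptance follows min(1, exp(-dH/T))", {
  set.seed(31)
  # always accept downhill
  expect_true(all(metropolis_accept(runif(100, -10, 0), 2)))
  # forced dH = T*ln 2 accepts with probability 1/2
  n <- 20000
  acc <- metropolis_accept(rep(10 * log(2), n), 10)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(acc) - 0.5), 3 * se)
})

test_that("quench limit: energy is non-increasing at vanishing temperature", {
  v <- generate_spheroid(spheroid_spec(n_cells = 10, radius = 8, seed = 10))
  st <- init_state(v, params = model_params())
  p <- model_params(temperature = 1e-8, lambda_V = 1, lambda_A = 0.1)
  set.seed(2)
  st <- mcs_step(st, p, n = 10)
  tr <- attr(st, "h_trace")
  expect_true(all(diff(tr) <= 1e-9))
})

test_that("strong constraints pin volumes to their targets", {
  v <- generate_spheroid(spheroid_spec(n_cells = 10, radius = 8, seed = 11))
  st <- init_state(v, params = model_params())
  p <- model_params(lambda_V = 1e5, lambda_A = 1e4, temperature = 10)
  set.seed(9)
  st <- mcs_step(st, p, n = 50)
  cells <- st$cells[st$cells$celltype == "Cell", ]
  expect_true(all(abs(cells$volume - cells$target_volume) <= 1))
})

test_that("trajectories are deterministic under a fixed seed", {
  v <- generate_spheroid(spheroid_spec(n_cells = 8, radius = 7, seed = 12))
  p <- model_params(n_mcs = 12, seed = 123)
  t1 <- run_simulation(init_state(v, params = p), p, report_interval = 4)
  t2 <- run_simulation(init_state(v, params = p), p, report_interval = 4)
  expect_identical(t1$state$lattice, t2$state$lattice)
  expect_identical(t1$reports, t2$reports)
  expect_identical(t1$h_trace, t2$h_trace)
  expect_length(t1$h_trace, 13)
  # n_mcs = 0: only the initial report
  p0 <- model_params(n_mcs = 0)
  t0 <- run_simulation(init_state(v, params = p0), p0)
  expect_identical(t0$reports$mcs, 0L)
  expect_equal(t0$reports$wip, 0)
})

test_that("run_simulation reports agree with the tracked state and write snapshots", {
  v <- generate_spheroid(spheroid_spec(n_cells = 8, radius = 7, seed = 14))
  p <- model_params(n_mcs = 9, seed = 4, lambda_V = 50, lambda_A = 5)
  dir <- withr::local_tempdir()
  tr <- run_simulation(init_state(v, params = p), p, snapshot_interval = 3,
                       report_interval = 3, out_dir = dir)
  # sum of reported per-cell volumes equals the bookkept cell volumes at
  # the end (cells exchange voxels with medium, so it need not be constant)
  cells <- tr$state$cells[tr$state$cells$celltype == "Cell", ]
  last <- tr$reports[nrow(tr$reports), ]
  expect_equal(last$total_volume, sum(cells$volume))
  expect_equal(tr$reports$total_volume[1], sum(v$lattice > 0))
  expect_length(tr$snapshots, 4)   # MCS 0, 3, 6, 9
  snap <- read_label_tiff(tr$snapshots[[4]])
  expect_identical(snap$lattice, state_to_volume(tr$state)$lattice)
})

test_that("two-state toy chain samples the Boltzmann ratio", {
  # 5x3x3 lattice, three interior voxels in a row at x = 2, 3, 4. One cell
  # with target volume 1.5 (so V = 1 and V = 2 cost the same volume
  # penalty) and lambda_V large enough that vanishing (V = 0) or filling
  # the row (V = 3) costs ~ 2 * lambda_V and never happens on test
  # timescales. Starting from {site2}, the copy dynamics can only toggle
  # site3 (site2 has no non-wall neighbor but site3, so it can never be
  # retracted; site4 can only be invaded from site3, which would mean
  # V = 3): a genuine two-state chain A = {2} <-> B = {2, 3}, and the two
  # proposals (copy cell from site2 into site3 / copy medium from site4
  # into site3) are symmetric, so the stationary ratio is Boltzmann:
  # pi_B / pi_A = exp(-(E_B - E_A) / T), with E_B - E_A = 4 * J_cw (site3
  # trades a cell-medium face for a cell-cell face of zero J_cc, adds 4
  # wall faces, and the cell-medium face moves to site4).
  lv <- 200; Jcw <- 5; Jcm <- 10; Temp <- 10
  p <- model_params(lambda_V = lv, lambda_A = 0, J_cc = 0, J_cm = Jcm,
                    J_cw = Jcw, temperature = Temp)
  tgdf <- data.frame(cell_id = 1L, target_volume = 1.5, target_surface = 0)
  vA <- make_vol(c(5, 3, 3)); vA$lattice[2, 2, 2] <- 1L
  vB <- make_vol(c(5, 3, 3)); vB$lattice[2:3, 2, 2] <- 1L
  stA <- init_state(vA, tgdf, p)
  stB <- init_state(vB, tgdf, p)
  gap <- hamiltonian(stB, p) - hamiltonian(stA, p)
  expect_equal(gap, 4 * Jcw)   # analytic energy gap

  set.seed(41)
  st <- stA
  n <- 20000L
  n_b <- 0L
  for (i in seq_len(n)) {
    st <- mcs_step(st, p, n = 1)
    vol_now <- st$cells$volume[1]
    if (!vol_now %in% c(1, 2)) stop("left the two-state class")
    n_b <- n_b + (vol_now == 2)
  }
  expect_equal(st$lattice[2, 2, 2], 1L)   # site2 never retracts
  ratio <- exp(-gap / Temp)
  expect_lt(abs(n_b / n - ratio / (1 + ratio)), 0.05)
})
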