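test_that("labeling keeps all, none, or the expected fraction of sites", {
  occ <- matrix(1L, 2, 500)
  s1 <- observation_settings(labeled_fraction = 1, labeling_mode = "per-snapshot")
  expect_equal(apply_labeling(occ, s1), occ)
  s0 <- observation_settings(labeled_fraction = 0, labeling_mode = "per-snapshot")
  expect_equal(sum(apply_labeling(occ, s0)), 0)
  # binomial mean: visible count ~ 0.2 * occupied, within 3 SD
  sp <- observation_settings(labeled_fraction = 0.2, labeling_mode = "per-snapshot")
  set.seed(41)
  occ_big <- matrix(1L, 2, 5000)
  vis <- sum(apply_labeling(occ_big, sp))
  n <- length(occ_big)
  expect_lt(abs(vis - 0.2 * n), 3 * sqrt(n * 0.2 * 0.8))
  # empty sites never light up
  expect_equal(sum(apply_labeling(matrix(0L, 2, 100), s1)), 0)
})

test_that("per-molecule labels are persistent across snapshots", {
  set.seed(42)
  p <- lattice_params(k_on = 2, k_off = 1, w = 2, c = 1, v_grow = 0,
                      n0 = 20, max_time = 40)
  tr <- simulate_lattice(p, snapshot_times = c(10, 20, 30),
                         stop_when_filled = FALSE)
  st <- observation_settings(labeled_fraction = 0.5)
  labels <- molecule_labels(tr$n_molecules, 0.5)
  # a molecule visible in one frame is visible whenever it is present
  vis <- lapply(tr$snapshots, apply_labeling, settings = st, labels = labels)
  for (f in 1:3) {
    m <- tr$snapshots[[f]]
    expect_equal(vis[[f]][m > 0], as.integer(labels[m[m > 0]]))
  }
})

test_that("broadening is a clipped dilation", {
  # one visible site near the pointed end lights its 4-site neighbourhood,
  # clipped at the end: sites 1..6 of 10
  row <- integer(10); row[2] <- 1L
  expect_equal(which(broaden(row, 4) == 1L), 1:6)
  expect_equal(broaden(integer(8), 4), integer(8))
  # two sites 3 apart merge into one contiguous run
  row2 <- integer(20); row2[c(8, 11)] <- 1L
  lit <- which(broaden(row2, 4) == 1L)
  expect_equal(lit, 4:15)
  expect_true(all(diff(lit) == 1))
  # idempotent at fixed radius; monotone in the input
  b1 <- broaden(row2, 4)
  expect_equal(broaden(b1, 0), b1)
  row3 <- row2; row3[15] <- 1L
  expect_true(all(broaden(row3, 4) >= b1))
})

test_that("groove summation yields levels 0, 1, 2", {
  expect_equal(sum_rows(c(0, 1, 1), c(0, 0, 1)), c(0L, 1L, 2L))
})

test_that("coverage fractions follow the occupancy accounting rules", {
  expect_equal(coverage_summary(matrix(1L, 2, 7)),
               tibble::tibble(total_occupancy = 1, single_fraction = 0,
                              double_fraction = 1))
  one_row <- rbind(rep(1L, 5), rep(0L, 5))
  expect_equal(coverage_summary(one_row)$total_occupancy, 0.5)
  expect_equal(coverage_summary(one_row)$single_fraction, 1)
  hand <- rbind(c(1, 1, 0, 0), c(1, 0, 0, 0))
  out <- coverage_summary(hand)
  expect_equal(out$total_occupancy, 0.375)
  expect_equal(out$single_fraction, 0.25)
  expect_equal(out$double_fraction, 0.25)
  # identity total = (single + 2 double) / 2 on random occupancies
  set.seed(43)
  for (k in 1:20) {
    occ <- matrix(rbinom(40, 1, runif(1)), 2, 20)
    cs <- coverage_summary(occ)
    expect_equal(cs$total_occupancy,
                 (cs$single_fraction + 2 * cs$double_fraction) / 2)
  }
  expect_error(coverage_summary(matrix(integer(0), 2, 0)), "zero-length")
})

test_that("processing order is label -> broaden -> sum, not the reverse", {
  # broadening before labeling thins the dilated mask instead of dilating
  # the thinned mask; the two pipelines must differ
  set.seed(44)
  occ <- matrix(0L, 2, 60)
  occ[1, 20:40] <- 1L
  st <- observation_settings(labeled_fraction = 0.3,
                             labeling_mode = "per-snapshot")
  set.seed(1); a <- tpmcable:::process_snapshot(occ, st)
  set.seed(1)
  swapped <- apply_labeling(rbind(broaden(occ[1, ], 4), broaden(occ[2, ], 4)),
                            st)
  b <- sum_rows(swapped[1, ], swapped[2, ])
  expect_false(identical(a, b))
  expect_gt(sum(a), sum(b))  # dilating after thinning lights more sites
})

test_that("coverage at target length hits the trivial limits", {
  st <- observation_settings()
  # no binding: zero fluorescence
  p0 <- lattice_params(k_on = 0, k_off = 1, v_grow = 5, n0 = 1,
                       max_time = 100, seed = 2)
  out0 <- coverage_at_length(p0, st, target_length_um = 0.5, n_rep = 3)
  expect_equal(out0$mean_fluorescence, rep(0, 3))
  # saturating binding, full labeling, no broadening: level ~ 2 everywhere
  # (just-appended barbed-end columns are naked at the read-out instant,
  # so the level approaches 2 from below as the filament lengthens)
  set.seed(3)
  psat <- lattice_params(k_on = 1000, k_off = 1, w = 1, c = 1, v_grow = 2,
                         n0 = 1, max_time = 100)
  s2 <- observation_settings(labeled_fraction = 1, broadening_radius_sites = 0)
  outs <- coverage_at_length(psat, s2, target_length_um = 2, n_rep = 3)
  expect_gt(mean(outs$mean_fluorescence), 1.95)
  # unreachable target errors, naming max_time
  pbad <- lattice_params(k_on = 0, k_off = 1, v_grow = 0.01, n0 = 1,
                         max_time = 5, seed = 2)
  expect_error(coverage_at_length(pbad, st, target_length_um = 6, n_rep = 1),
               "max_time")
})

test_that("coverage is half-maximal at the oracle-located midpoint", {
  K_mid <- tpmcable:::equilibrium_midpoint_K(w = 3, c = 1.5, N = Inf)
  set.seed(6)
  p <- lattice_params(k_on = K_mid * 10, k_off = 10, w = 3, c = 1.5,
                      v_grow = 2.2, max_time = 400)
  run <- coverage_at_length(p, observation_settings(), target_length_um = 2,
                            n_rep = 24)
  se <- sd(run$total_occupancy) / sqrt(24)
  expect_lt(abs(mean(run$total_occupancy) - 0.5), 3 * se + 0.02)
})

test_that("kymographs honour the sentinel and the trivial settings", {
  p0 <- lattice_params(k_on = 0, k_off = 1, v_grow = 1, n0 = 1,
                       max_time = 30, seed = 9)
  tr0 <- simulate_lattice(p0, snapshot_times = seq(5, 30, 5))
  ky0 <- render_kymograph(tr0, observation_settings())
  expect_true(all(ky0$intensity %in% c(-1L, 0L)))
  expect_true(any(ky0$intensity == -1L))  # early frames end before max N
  # full labeling, no broadening: kymograph equals the summed raw occupancy
  set.seed(10)
  p <- lattice_params(k_on = 3, k_off = 1, w = 2, c = 1, v_grow = 1,
                      n0 = 1, max_time = 30)
  tr <- simulate_lattice(p, snapshot_times = seq(5, 30, 5))
  ky <- render_kymograph(tr, observation_settings(labeled_fraction = 1,
                                                  broadening_radius_sites = 0))
  for (f in seq_along(tr$snapshots)) {
    m <- (tr$snapshots[[f]] > 0) + 0L
    raw <- colSums(m)
    expect_equal(unname(ky$intensity[f, seq_along(raw)]), raw)
  }
  # replay determinism
  pp <- lattice_params(k_on = 3, k_off = 1, w = 2, c = 1, v_grow = 1,
                       n0 = 1, max_time = 30, seed = 77)
  k1 <- render_kymograph(simulate_lattice(pp, snapshot_times = seq(5, 30, 5)))
  k2 <- render_kymograph(simulate_lattice(pp, snapshot_times = seq(5, 30, 5)))
  expect_identical(k1$intensity, k2$intensity)
})

test_that("boundary velocities are recovered from synthetic cables", {
  # cable advancing exactly one site per frame at the barbed edge
  n_fr <- 30
  im <- matrix(0L, n_fr, 60)
  for (f in 1:n_fr) im[f, 10:(20 + f)] <- 1L
  ky <- make_kymograph(im, frame_interval = 2)
  v <- estimate_boundary_velocity(ky)
  expect_equal(v$velocity_sites_per_s[v$direction == "barbed"], 0.5,
               tolerance = 1e-8)
  expect_equal(v$velocity_sites_per_s[v$direction == "pointed"], 0,
               tolerance = 1e-8)
  # static cable: both edges at zero velocity
  im2 <- matrix(0L, n_fr, 60); im2[, 25:35] <- 1L
  v2 <- estimate_boundary_velocity(make_kymograph(im2, 2))
  expect_equal(v2$velocity_sites_per_s, c(0, 0))
  # too-short persistence: no qualifying window
  im3 <- matrix(0L, 5, 60); im3[, 25:35] <- 1L
  expect_equal(nrow(estimate_boundary_velocity(make_kymograph(im3, 2))), 0)
})

test_that("spreading velocity of a simulated cable matches the zipper rate", {
  # seeded nucleus, spontaneous nucleation suppressed (k_on/k_off ~ 2e-5);
  # net edge speed is k_on w - k_off / w
  set.seed(3)
  N <- 100
  init <- empty_lattice(N)
  init$occupancy[1, 48:53] <- 1L
  expected <- 0.005 * 400 - 300 / 400
  vels <- vapply(1:12, function(r) {
    p <- lattice_params(k_on = 0.005, k_off = 300, w = 400, c = 1,
                        v_grow = 0, n0 = N, max_time = 30)
    tr <- simulate_lattice(p, record_events = FALSE,
                           snapshot_times = seq(0.5, 30, 0.5),
                           stop_when_filled = FALSE, init_state = init)
    ky <- render_kymograph(tr, observation_settings(labeled_fraction = 1,
                                                    broadening_radius_sites = 0))
    v <- estimate_boundary_velocity(ky, min_window_s = 15)
    if (nrow(v)) mean(v$velocity_sites_per_s) else NA_real_
  }, numeric(1))
  expect_lt(abs(mean(vels, na.rm = TRUE) - expected) / expected, 0.25)
})
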