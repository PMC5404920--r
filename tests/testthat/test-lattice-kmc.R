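test_that("local on-rates combine neighbour and cross-strand factors", {
  p <- lattice_params(k_on = 1, k_off = 300, w = 40, c = 1.25, v_grow = 0,
                      n0 = 5, max_time = 1)
  s <- empty_lattice(5)
  # empty lattice: base rate everywhere
  expect_equal(local_on_rate(s, p, 3, 1), 1)
  expect_equal(local_on_rate(s, p, 1, 2), 1)
  # both same-row neighbours occupied, opposite empty -> k_on * w^2
  s$occupancy[1, c(2, 4)] <- 1L
  expect_equal(local_on_rate(s, p, 3, 1), 1 * 40^2)
  # one neighbour + opposite occupied -> k_on * w * c = 50
  s2 <- empty_lattice(5)
  s2$occupancy[1, 2] <- 1L
  s2$occupancy[2, 3] <- 1L
  expect_equal(local_on_rate(s2, p, 3, 1), 50)
  # ends have a single neighbour
  s3 <- empty_lattice(5)
  s3$occupancy[1, 2] <- 1L
  expect_equal(local_on_rate(s3, p, 1, 1), 40)
  # contract violations
  expect_error(local_on_rate(s2, p, 2, 1), "occupied")
  expect_error(local_on_rate(s, p, 9, 1), "out of range")
})

test_that("local off-rates are divided by the cooperativity factors", {
  p <- lattice_params(k_on = 1, k_off = 300, w = 125, c = 1.25, v_grow = 0,
                      n0 = 5, max_time = 1)
  s <- empty_lattice(5)
  s$occupancy[1, 3] <- 1L
  # isolated molecule leaves at the base off-rate
  expect_equal(local_off_rate(s, p, 3, 1), 300)
  # flanked within a cable and across from a bound molecule:
  # k_off / w^2 / c = 300 / 125^2 / 1.25
  s$occupancy[1, c(2, 4)] <- 1L
  s$occupancy[2, 3] <- 1L
  expect_equal(local_off_rate(s, p, 3, 1), 300 / 125^2 / 1.25)
  expect_equal(local_off_rate(s, p, 3, 1), 0.01536)
  expect_error(local_off_rate(s, p, 5, 1), "empty")
})

test_that("growth sets N = floor(t * v_grow), clamped and zero-filled", {
  s <- empty_lattice(5)
  s$occupancy[1, 2] <- 1L
  g <- apply_growth(s, new_time = 10.3, v_grow = 2)
  expect_equal(g$N, 20)
  expect_equal(g$occupancy[1, 2], 1L)
  expect_true(all(g$occupancy[, 6:20] == 0L))
  # v_grow = 0 leaves N unchanged; N never decreases
  expect_equal(apply_growth(s, 100, 0)$N, 5)
  expect_equal(apply_growth(g, g$t + 0.01, 0.1)$N, 20)
  expect_error(apply_growth(s, -1, 2), "new_time")
})

test_that("total propensity matches the closed forms on empty/full lattices", {
  p <- lattice_params(k_on = 0.7, k_off = 1.3, w = 13, c = 2, v_grow = 0,
                      n0 = 6, max_time = 1)
  expect_equal(total_propensity(empty_lattice(6), p), 2 * 6 * 0.7)
  p1 <- lattice_params(k_on = 0.7, k_off = 1.3, w = 1, c = 1, v_grow = 0,
                       n0 = 6, max_time = 1)
  full <- lattice_state(matrix(1L, 2, 6))
  expect_equal(total_propensity(full, p1), 2 * 6 * 1.3)
})

test_that("Gillespie waiting times are exponential with the total rate", {
  p <- lattice_params(k_on = 0.4, k_off = 2, w = 3, c = 2, v_grow = 0.5,
                      n0 = 4, max_time = 1)
  s <- empty_lattice(4)
  s$occupancy[1, 2] <- 1L
  rate <- total_propensity(s, p)
  set.seed(11)
  dts <- vapply(1:4000, function(k) kmc_step(s, p)$dt, numeric(1))
  expect_gt(ks.test(dts, "pexp", rate)$p.value, 0.01)
})

test_that("event selection frequencies follow the propensities", {
  p <- lattice_params(k_on = 0.4, k_off = 2, w = 3, c = 2, v_grow = 0.5,
                      n0 = 2, max_time = 1)
  s <- empty_lattice(2)
  s$occupancy[2, 1] <- 1L
  rates <- c(tpmcable:::all_site_rates(s, p)[1, ],
             tpmcable:::all_site_rates(s, p)[2, ], p$v_grow)
  set.seed(12)
  n <- 4000
  picks <- vapply(seq_len(n), function(k) {
    ev <- kmc_step(s, p)$event
    if (ev$type == "grow") 5L else (ev$row - 1L) * 2L + ev$site
  }, integer(1))
  obs <- tabulate(picks, 5)
  expect_gt(stats::chisq.test(obs, p = rates / sum(rates))$p.value, 0.001)
})

test_that("simulation respects trivial limits and is seed-reproducible", {
  # k_on = 0: nothing ever binds
  p0 <- lattice_params(k_on = 0, k_off = 1, v_grow = 2, n0 = 1,
                       max_time = 20, seed = 4)
  tr0 <- simulate_lattice(p0)
  expect_equal(sum(tr0$final_state$occupancy), 0)
  expect_true(all(tr0$events$event == "grow"))
  # identical seed => bit-identical trajectory
  p <- lattice_params(k_on = 1, k_off = 1, w = 2, c = 1.5, v_grow = 1,
                      n0 = 2, max_time = 30, seed = 99)
  a <- simulate_lattice(p)
  b <- simulate_lattice(p)
  expect_identical(a$events, b$events)
  expect_identical(a$final_molecules, b$final_molecules)
})

test_that("event log replays to the final state; times increase; N grows", {
  p <- lattice_params(k_on = 2, k_off = 2, w = 3, c = 1.5, v_grow = 1.5,
                      n0 = 2, max_time = 40, seed = 21)
  tr <- simulate_lattice(p)
  expect_true(all(diff(tr$events$time) > 0))
  grows <- tr$events$site[tr$events$event == "grow"]
  expect_true(all(diff(grows) >= 0))
  expect_true(all(tr$final_state$occupancy %in% c(0L, 1L)))
  rep_state <- replay_trajectory(tr)
  expect_equal(rep_state$occupancy, tr$final_state$occupancy)
  # replay with an occupied initial state
  ini <- empty_lattice(6); ini$occupancy[1, 2:4] <- 1L
  p2 <- lattice_params(k_on = 1, k_off = 3, w = 4, c = 1, v_grow = 0,
                       n0 = 6, max_time = 10, seed = 5)
  tr2 <- simulate_lattice(p2, init_state = ini, stop_when_filled = FALSE)
  expect_equal(replay_trajectory(tr2)$occupancy, tr2$final_state$occupancy)
})

test_that("fixed symmetric lattice relaxes to half coverage", {
  p <- lattice_params(k_on = 1, k_off = 1, w = 1, c = 1, v_grow = 0,
                      n0 = 10, max_time = 1500, seed = 7)
  tc <- time_averaged_coverage(p, n_rep = 6)
  se <- sd(tc$coverage) / sqrt(nrow(tc))
  expect_lt(abs(mean(tc$coverage) - 0.5), 3 * se + 3e-3)
})

test_that("empirical configuration frequencies follow the stationary law", {
  # N = 2 lattice: sample configurations at regular times and compare with
  # pi(config) ~ K^n (w^2)^p_row (c^2)^p_cross computed independently
  K <- 0.8; w <- 2; c <- 1.5
  p <- lattice_params(k_on = K, k_off = 1, w = w, c = c, v_grow = 0,
                      n0 = 2, max_time = 6000, seed = 13)
  tr <- simulate_lattice(p, record_events = FALSE,
                         snapshot_times = seq(10, 6000, by = 0.75),
                         stop_when_filled = FALSE)
  ids <- vapply(tr$snapshots, function(m) {
    occ <- (m > 0) + 0L
    1L + occ[1, 1] + 2L * occ[2, 1] + 4L * occ[1, 2] + 8L * occ[2, 2]
  }, integer(1))
  obs <- tabulate(ids, 16) / length(ids)
  configs <- expand.grid(a = 0:1, b = 0:1, d = 0:1, e = 0:1)
  pi_exp <- apply(configs, 1, function(v)
    config_weight(rbind(c(v[1], v[3]), c(v[2], v[4])), K, w, c))
  pi_exp <- pi_exp / sum(pi_exp)
  # correlated samples: generous absolute tolerance per configuration
  expect_lt(max(abs(obs - pi_exp)), 0.02)
})

test_that("rows are statistically independent when w = c = 1", {
  p <- lattice_params(k_on = 1, k_off = 1, w = 1, c = 1, v_grow = 0,
                      n0 = 6, max_time = 4000, seed = 17)
  tr <- simulate_lattice(p, record_events = FALSE,
                         snapshot_times = seq(5, 4000, by = 1),
                         stop_when_filled = FALSE)
  r1 <- vapply(tr$snapshots, function(m) sum(m[1, ] > 0), numeric(1))
  r2 <- vapply(tr$snapshots, function(m) sum(m[2, ] > 0), numeric(1))
  expect_lt(abs(cor(r1, r2)), 0.06)
})

test_that("deterministic growth tracks floor(t * v_grow)", {
  p <- lattice_params(k_on = 0.5, k_off = 0.5, v_grow = 2, n0 = 1,
                      max_time = 25, seed = 31, deterministic_growth = TRUE)
  tr <- simulate_lattice(p)
  expect_gte(tr$final_state$N, floor(tr$final_state$t * 2) - 1)
  expect_equal(tr$status, "max_time")
})
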