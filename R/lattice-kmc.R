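# Kinetic Monte Carlo simulation of cooperative tropomyosin loading on a
# growing two-row lattice.  The event loop lives in C++ (src/kmc.cpp); the
# per-site rate functions and a single Gillespie step are also available in
# plain R as the readable reference implementation, and the two paths are
# cross-checked in the test suite.

neighbour_count <- function(occupancy, i, j) {
  N <- ncol(occupancy)
  (i > 1 && occupancy[j, i - 1] == 1L) + (i < N && occupancy[j, i + 1] == 1L)
}

#' Local association and dissociation rates
#'
#' `local_on_rate()` returns the association propensity of an *empty* site
#' `(i, j)`: `k_on * w^a * c^b`.  `local_off_rate()` returns the
#' dissociation propensity of an *occupied* site: `k_off / (w^a * c^b)`.
#' Here `a` is the number of occupied immediate neighbours in the same row
#' (filament ends have only one neighbour) and `b` the occupancy of site
#' `(i, 3-j)` in the opposite row.
#'
#' @param state A [lattice_state()].
#' @param params A [lattice_params()].
#' @param i Site index (1-based; 1 = pointed end).
#' @param j Row index (1 or 2).
#' @return Rate in s^-1.
#' @export
#' @examples
#' p <- lattice_params(k_on = 1, k_off = 300, w = 40, c = 1.25)
#' s <- empty_lattice(5)
#' local_on_rate(s, p, 3, 1)  # k_on: no neighbours
local_on_rate <- function(state, params, i, j) {
  check_site_index(state, i, j)
  if (state$occupancy[j, i] != 0L)
    abort("local_on_rate() called on an occupied site")
  a <- neighbour_count(state$occupancy, i, j)
  b <- state$occupancy[3 - j, i]
  params$k_on * params$w^a * params$c^b
}

#' @rdname local_on_rate
#' @export
local_off_rate <- function(state, params, i, j) {
  check_site_index(state, i, j)
  if (state$occupancy[j, i] != 1L)
    abort("local_off_rate() called on an empty site")
  a <- neighbour_count(state$occupancy, i, j)
  b <- state$occupancy[3 - j, i]
  params$k_off / (params$w^a * params$c^b)
}

check_site_index <- function(state, i, j) {
  if (length(i) != 1 || length(j) != 1 || i < 1 || i > state$N || !j %in% c(1, 2))
    abort(sprintf("site index (%s, %s) out of range for N = %d", i, j, state$N))
  invisible(TRUE)
}

all_site_rates <- function(state, params) {
  # propensity matrix in the fixed selection order: row 1 sites, row 2 sites
  occ <- state$occupancy
  N <- ncol(occ)
  r <- matrix(0, 2, N)
  for (j in 1:2) {
    for (i in seq_len(N)) {
      r[j, i] <- if (occ[j, i] == 1L) local_off_rate(state, params, i, j)
                 else local_on_rate(state, params, i, j)
    }
  }
  r
}

#' One Gillespie step of the lattice model (reference implementation)
#'
#' Draws an exponential waiting time from the total propensity (all
#' per-site on/off rates plus the growth rate `v_grow`), selects one event
#' by cumulative-sum search in fixed order (row 1 sites, row 2 sites,
#' growth last), and applies it.  Used for illustration and as the
#' independent reference for the compiled event loop; use
#' [simulate_lattice()] for production runs.
#'
#' @inheritParams local_on_rate
#' @return A list with the updated `state`, the waiting time `dt`, and an
#'   `event` record (type, site, row), or a signal of the absorbing state
#'   (`event$type == "absorbing"`) when the total propensity is zero.
#' @export
kmc_step <- function(state, params) {
  rates <- all_site_rates(state, params)
  growth_rate <- if (params$deterministic_growth) 0 else params$v_grow
  total <- sum(rates) + growth_rate
  if (total <= 0) {
    return(list(state = state, dt = Inf,
                event = list(type = "absorbing", site = NA, row = NA)))
  }
  dt <- rexp(1, total)
  new_time <- state$t + dt
  u <- runif(1) * total
  # cumulative order: row 1 left-to-right, row 2 left-to-right, growth last
  flat <- c(rates[1, ], rates[2, ])
  cs <- cumsum(flat)
  occ <- state$occupancy
  if (u < cs[length(cs)]) {
    k <- which(u < cs)[1]
    N <- ncol(occ)
    j <- if (k <= N) 1L else 2L
    i <- if (k <= N) k else k - N
    occ[j, i] <- 1L - occ[j, i]
    ev <- list(type = if (occ[j, i] == 1L) "bind" else "unbind",
               site = i, row = j)
    state <- lattice_state(occ, t = new_time)
  } else {
    state <- lattice_state(occ, t = new_time)
    state <- apply_growth(state, new_time, params$v_grow)
    ev <- list(type = "grow", site = state$N, row = NA)
  }
  list(state = state, dt = dt, event = ev)
}

#' Apply a filament growth event
#'
#' Sets the site count to `floor(new_time * v_grow)`, clamped so that N
#' never decreases; newly appended barbed-end sites are unoccupied in both
#' rows.
#'
#' @param state A [lattice_state()].
#' @param new_time Time of the growth event (s), `>= state$t`.
#' @param v_grow Growth rate in sites/s.
#' @return The updated `lattice_state`.
#' @export
#' @examples
#' apply_growth(empty_lattice(5), new_time = 10.3, v_grow = 2)$N  # 20
apply_growth <- function(state, new_time, v_grow) {
  if (new_time < state$t) abort("new_time must be >= state$t")
  n_new <- max(state$N, floor(new_time * v_grow))
  occ <- state$occupancy
  if (n_new > state$N)
    occ <- cbind(occ, matrix(0L, 2, n_new - state$N))
  lattice_state(occ, t = new_time)
}

#' Simulate the lattice model
#'
#' Runs the kinetic Monte Carlo event loop until `max_time`, until the
#' lattice is completely filled (fixed lattice, `v_grow = 0`), or until the
#' filament reaches `stop_at_sites` sites.  Randomness comes from R's RNG:
#' set a seed via `params$seed` or `set.seed()` for bit-identical replays.
#'
#' @param params A [lattice_params()].
#' @param record_events Keep the full event log (time, type, site, row,
#'   molecule id)?  Turn off for long coverage runs.
#' @param snapshot_times Numeric vector of times at which to record the
#'   full occupancy (as matrices of persistent molecule ids, 0 = empty).
#'   A snapshot at time s records the state just before s.
#' @param stop_at_sites Stop as soon as the filament has at least this many
#'   sites (0 = never).
#' @param burnin Time before which occupancy is excluded from the
#'   time-average accumulator.
#' @param max_events Safety cap on the number of events.
#' @param stop_when_filled Stop a fixed lattice (`v_grow = 0`) once every
#'   site is occupied (the model's run-termination rule).  Set `FALSE`
#'   for long-run equilibrium averages.
#' @param init_state Optional [lattice_state()] with `N = n0` columns used
#'   as the initial occupancy (default: empty lattice).  Pre-bound
#'   molecules get ids `1..n`.
#' @return A `lattice_trajectory`: list with `events` (tibble), `snapshots`
#'   (list of 2 x N integer molecule-id matrices), `final_state`,
#'   `final_molecules`, `n_molecules`, `status`, `mean_coverage` (the
#'   time-averaged per-site occupancy after `burnin`), and the `params`.
#' @export
#' @examples
#' p <- lattice_params(k_on = 0.5, k_off = 0.5, v_grow = 0, n0 = 10,
#'                     max_time = 50, seed = 1)
#' tr <- simulate_lattice(p)
simulate_lattice <- function(params, record_events = TRUE,
                             snapshot_times = numeric(0),
                             stop_at_sites = 0, burnin = 0,
                             max_events = 1e8, stop_when_filled = TRUE,
                             init_state = NULL) {
  stopifnot(inherits(params, "lattice_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  snapshot_times <- sort(snapshot_times)
  init <- NULL
  if (!is.null(init_state)) {
    stopifnot(inherits(init_state, "lattice_state"))
    if (init_state$N != params$n0)
      abort("init_state must have exactly n0 columns")
    init <- init_state$occupancy
  }
  res <- kmc_run_cpp(
    params$k_on, params$k_off, params$w, params$c, params$v_grow,
    params$n0, params$max_time, as.integer(stop_at_sites),
    params$deterministic_growth, record_events,
    as.numeric(snapshot_times), burnin, max_events, stop_when_filled, init
  )
  events <- NULL
  if (record_events) {
    events <- tibble::tibble(
      time = res$events$time,
      event = c("bind", "unbind", "grow")[res$events$type],
      site = res$events$site,
      row = res$events$row,
      molecule = res$events$molecule
    )
  }
  final_mol <- res$occupancy
  structure(
    list(
      params = params,
      events = events,
      snapshots = res$snapshots,
      snapshot_times = snapshot_times,
      final_state = lattice_state((final_mol > 0) + 0L, t = res$t),
      final_molecules = final_mol,
      n_molecules = res$n_molecules,
      init_occupancy = if (is.null(init)) matrix(0L, 2, params$n0) else init,
      status = res$status,
      mean_coverage = if (res$observed_time > 0)
        res$occupancy_time_integral / (res$observed_time * 2 * res$N) else NA_real_,
      observed_time = res$observed_time,
      n_events = res$n_events,
      seed = params$seed
    ),
    class = "lattice_trajectory"
  )
}

#' @export
print.lattice_trajectory <- function(x, ...) {
  cat(sprintf("<lattice_trajectory> t = %.3g s, N = %d sites, %d molecules seen, status: %s\n",
              x$final_state$t, x$final_state$N, x$n_molecules, x$status))
  if (!is.null(x$events)) cat(sprintf("  %d events logged\n", nrow(x$events)))
  invisible(x)
}

#' Replay an event log
#'
#' Reconstructs the occupancy from the initial empty lattice by applying
#' the logged events in order.  Replay of a trajectory's log reproduces its
#' final state exactly; used as an integrity check.
#'
#' @param trajectory A `lattice_trajectory` simulated with
#'   `record_events = TRUE`.
#' @param until Optional time: replay only events with `time <= until`.
#' @return A [lattice_state()].
#' @export
replay_trajectory <- function(trajectory, until = Inf) {
  ev <- trajectory$events
  if (is.null(ev)) abort("trajectory has no event log; rerun with record_events = TRUE")
  ev <- ev[ev$time <= until, , drop = FALSE]
  n_final <- if (any(ev$event == "grow")) max(ev$site[ev$event == "grow"],
                                              trajectory$params$n0)
             else trajectory$params$n0
  if (is.finite(until) == FALSE) n_final <- trajectory$final_state$N
  occ <- matrix(0L, 2, n_final)
  ini <- trajectory$init_occupancy
  occ[, seq_len(ncol(ini))] <- (ini > 0) + 0L
  for (k in seq_len(nrow(ev))) {
    if (ev$event[k] == "bind") occ[ev$row[k], ev$site[k]] <- 1L
    else if (ev$event[k] == "unbind") occ[ev$row[k], ev$site[k]] <- 0L
  }
  t_end <- if (nrow(ev)) max(ev$time) else 0
  lattice_state(occ, t = t_end)
}

#' Time-averaged coverage of a fixed lattice
#'
#' Convenience wrapper: simulates a non-growing lattice and returns the
#' time-averaged per-site occupancy after a burn-in, for comparison against
#' the exact equilibrium oracles.
#'
#' @inheritParams simulate_lattice
#' @param n_rep Number of independent replicates (their spread gives the
#'   standard error).
#' @return A tibble with one row per replicate and column `coverage`.
#' @export
time_averaged_coverage <- function(params, n_rep = 8, burnin = NULL,
                                   max_events = 1e8) {
  if (params$v_grow != 0)
    abort("time-averaged coverage is defined for fixed lattices (v_grow = 0)")
  if (is.null(burnin)) burnin <- 0.1 * params$max_time
  purrr::map_dfr(seq_len(n_rep), function(r) {
    tr <- simulate_lattice(params, record_events = FALSE, burnin = burnin,
                           max_events = max_events,
                           stop_when_filled = FALSE)
    tibble::tibble(rep = r, coverage = tr$mean_coverage,
                   n_events = tr$n_events)
  })
}
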