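# Seeded generators for every input table the pipeline consumes, each with
# known ground truth recorded as metadata, so downstream recovery is
# testable without any experimental data.

new_synthetic <- function(data, truth) {
  attr(data, "truth") <- truth
  class(data) <- c("synthetic_tbl", class(data))
  data
}

#' Ground truth of a synthetic table
#'
#' @param x A table from one of the `gen_*()` generators (or read back by
#'   [read_event_table()] with its metadata sidecar).
#' @return Named list of generating parameters (including the seed).
#' @export
synthetic_truth <- function(x) attr(x, "truth")

#' Synthetic first-binding events
#'
#' Draws `n` first-binding events on growing filaments via the
#' discrete-time Monte Carlo of [simulate_first_binding()].
#'
#' @param kon_len Per-length association rate (s^-1 nm^-1).
#' @param v_grow Growth rate (nm/s).
#' @param n Number of events.
#' @param seed RNG seed.
#' @param dt,max_time Passed to [first_binding_params()].
#' @return Event tibble with a `truth` attribute.
#' @export
gen_first_binding <- function(kon_len = 4e-6, v_grow = 47.5, n = 500,
                              seed = 1, dt = NULL, max_time = 2000) {
  p <- first_binding_params(kon_len = kon_len, v_grow = v_grow, dt = dt,
                            max_time = max_time, seed = seed)
  d <- simulate_first_binding(p, n = n)
  new_synthetic(d, list(table = "first_binding", kon_len = kon_len,
                        v_grow = v_grow, dt = p$dt, max_time = max_time,
                        n = n, seed = seed))
}

#' Synthetic second-binding geometries with overlap outcomes
#'
#' Samples filament/cable geometries on the 100-nm grid (uniform filament
#' lengths, cable lengths up to the filament, admissible start positions)
#' and draws each overlap flag Bernoulli(p2) under the true indirect
#' cooperativity `c_true`.  The defaults populate all three occupancy
#' bins.
#'
#' @param c_true True indirect cooperativity factor.
#' @param n Number of events (the observed-data scale is a few dozen).
#' @param seed RNG seed.
#' @param La_min,La_max Range of filament lengths (grid units).
#' @return Geometry tibble (`La`, `L1`, `x1`, `L2`, `overlapped`) with a
#'   `truth` attribute.
#' @export
gen_second_binding <- function(c_true = 1, n = 37, seed = 1,
                               La_min = 5, La_max = 60) {
  set.seed(seed)
  La <- sample(La_min:La_max, n, replace = TRUE)
  L1 <- vapply(La, function(l) sample.int(l, 1), 1L)
  x1 <- vapply(La - L1, function(m) sample.int(m + 1, 1) - 1L, 1L)
  L2 <- vapply(La, function(l) sample.int(l, 1), 1L)
  d <- tibble::tibble(La = La, L1 = L1, x1 = x1, L2 = L2)
  d <- overlap_probability(d, c = c_true)
  d$overlapped <- runif(n) < d$p2
  d <- d[, c("La", "L1", "x1", "L2", "overlapped")]
  new_synthetic(d, list(table = "second_binding", c_true = c_true, n = n,
                        seed = seed, La_min = La_min, La_max = La_max))
}

#' Synthetic residence times with right-censoring
#'
#' Exponential dwell times with mean `T1`, right-censored at
#' `censor_time` (molecules still bound when the observation window
#' ends).  The default `T1 = 13.7 s` corresponds to the effective
#' single-molecule off-rate `k_off / (w^2 c) ~ 0.073 s^-1` of the
#' end-to-end-only lattice parameter set (k_off = 116.8, w = 40, c = 1).
#'
#' @param T1 True mean residence time (s).
#' @param censor_time Observation window (s).
#' @param n Number of molecules.
#' @param seed RNG seed.
#' @return Residence tibble (`duration_s`, `censored`) with a `truth`
#'   attribute.
#' @export
gen_residence <- function(T1 = 13.7, censor_time = 60, n = 102, seed = 1) {
  set.seed(seed)
  raw <- rexp(n, rate = 1 / T1)
  censored <- raw > censor_time
  d <- tibble::tibble(duration_s = pmin(raw, censor_time),
                      censored = censored)
  new_synthetic(d, list(table = "residence", T1 = T1,
                        censor_time = censor_time, n = n, seed = seed))
}

#' Synthetic occupancy-versus-concentration curve
#'
#' Hill-shaped occupancies with additive truncated Gaussian noise,
#' clipped to [0, 1].  Defaults mimic a steep tropomyosin titration
#' (Hill n ~ 14.6, half-maximal near 1.2 uM free dimer).
#'
#' @param n_hill True Hill coefficient.
#' @param ec50 True half-maximal concentration (uM).
#' @param concentrations Concentrations to sample (uM); the default is an
#'   11-point titration spanning both plateaus.
#' @param sigma SD of the additive noise on occupancy.
#' @param seed RNG seed.
#' @return Curve tibble (`concentration`, `occupancy`) with a `truth`
#'   attribute.
#' @export
gen_occupancy_curve <- function(n_hill = 14.6, ec50 = 1.2,
                                concentrations = NULL, sigma = 0.02,
                                seed = 1) {
  set.seed(seed)
  if (is.null(concentrations))
    concentrations <- ec50 * c(0.2, 0.4, 0.6, 0.8, 0.9, 1, 1.1, 1.25, 1.6,
                               2, 2.5)
  th <- concentrations^n_hill / (ec50^n_hill + concentrations^n_hill)
  obs <- pmin(pmax(th + stats::rnorm(length(th), 0, sigma), 0), 1)
  d <- tibble::tibble(concentration = concentrations, occupancy = obs)
  new_synthetic(d, list(table = "occupancy_curve", n_hill = n_hill,
                        ec50 = ec50, sigma = sigma, seed = seed,
                        concentrations = concentrations))
}
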