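# Parameter and state containers for the two-row lattice model.

#' Parameters of the two-row lattice binding model
#'
#' Bundles the kinetic parameters of tropomyosin loading on a growing
#' actin filament.  The filament is a lattice of two rows (the two
#' helical grooves, each holding one tropomyosin cable) by N sites.  An
#' empty site binds at `k_on * w^a * c^b` and an occupied site unbinds at
#' `k_off / (w^a * c^b)`, where `a` counts occupied immediate same-row
#' neighbours (0-2, fewer at the filament ends) and `b` is the occupancy
#' of the opposite-groove site.  `w` is the end-to-end cooperativity
#' factor, `c` the indirect (cross-strand) cooperativity factor.
#'
#' @param k_on Base per-site association rate (s^-1).
#' @param k_off Base per-site dissociation rate (s^-1).
#' @param w End-to-end cooperativity factor (dimensionless, >= 0).
#' @param c Indirect cooperativity factor (dimensionless, >= 0).
#' @param v_grow Filament growth rate in sites/s.  Default 2.2 sites/s
#'   (about 47.5 nm/s at 21.6 nm per site), a typical barbed-end
#'   elongation rate at 1.5 uM Mg-ATP-actin.
#' @param site_length_nm Physical length of one site in nm.
#' @param n0 Initial site count (>= 1).
#' @param max_time Simulation horizon in seconds.
#' @param seed Optional RNG seed recorded with trajectories.
#' @param deterministic_growth If `TRUE`, the site count is updated
#'   deterministically as `floor(t * v_grow)` at every event instead of
#'   through a stochastic growth event of rate `v_grow` (the default).
#' @return A `lattice_params` object (a validated list).
#' @export
#' @examples
#' p <- lattice_params(k_on = 1, k_off = 116.8, w = 40, max_time = 100)
lattice_params <- function(k_on, k_off, w = 1, c = 1, v_grow = 2.2,
                           site_length_nm = 21.6, n0 = 1, max_time = 100,
                           seed = NULL, deterministic_growth = FALSE) {
  stopifnot(
    is.numeric(k_on), length(k_on) == 1, k_on >= 0,
    is.numeric(k_off), length(k_off) == 1, k_off >= 0,
    is.numeric(w), length(w) == 1, w >= 0,
    is.numeric(c), length(c) == 1, c >= 0,
    is.numeric(v_grow), length(v_grow) == 1, v_grow >= 0,
    is.numeric(site_length_nm), site_length_nm > 0,
    is.numeric(n0), n0 >= 1, n0 == as.integer(n0),
    is.numeric(max_time), max_time > 0
  )
  structure(
    list(
      k_on = k_on, k_off = k_off, w = w, c = c, v_grow = v_grow,
      site_length_nm = site_length_nm, n0 = as.integer(n0),
      max_time = max_time, seed = seed,
      deterministic_growth = isTRUE(deterministic_growth)
    ),
    class = "lattice_params"
  )
}

#' @export
print.lattice_params <- function(x, ...) {
  cat("<lattice_params>\n")
  cat(sprintf("  k_on = %g /s, k_off = %g /s, w = %g, c = %g\n",
              x$k_on, x$k_off, x$w, x$c))
  cat(sprintf("  v_grow = %g sites/s (%s), site = %g nm, n0 = %d, max_time = %g s\n",
              x$v_grow,
              if (x$deterministic_growth) "deterministic" else "stochastic event",
              x$site_length_nm, x$n0, x$max_time))
  invisible(x)
}

#' Construct a lattice state
#'
#' A `lattice_state` is a 2 x N binary occupancy matrix (rows = grooves,
#' columns = sites, site 1 being the pointed end) together with the
#' current time.  Growth appends sites at the barbed end (largest index).
#'
#' @param occupancy 2 x N matrix with entries 0/1.
#' @param t Current time in seconds.
#' @return A `lattice_state` object.
#' @export
#' @examples
#' s <- lattice_state(matrix(0L, 2, 5))
lattice_state <- function(occupancy, t = 0) {
  occupancy <- as.matrix(occupancy)
  if (nrow(occupancy) != 2 || ncol(occupancy) < 1)
    abort("occupancy must be a 2 x N matrix with N >= 1")
  if (!all(occupancy %in% c(0, 1)))
    abort("occupancy entries must be exactly 0 or 1")
  storage.mode(occupancy) <- "integer"
  structure(list(occupancy = occupancy, t = t, N = ncol(occupancy)),
            class = "lattice_state")
}

#' @rdname lattice_state
#' @param n Number of sites.
#' @export
empty_lattice <- function(n, t = 0) lattice_state(matrix(0L, 2, n), t = t)

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("<lattice_state> N = %d sites, t = %g s, %d occupied\n",
              x$N, x$t, sum(x$occupancy)))
  invisible(x)
}
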