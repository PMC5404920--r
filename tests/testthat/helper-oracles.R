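# Independent oracles used across the suite.

# literal per-placement enumerator for the second-binding counts: walks
# every start position x, evaluates the branch conditions and the clamped
# terms one by one (no vectorisation, no shared code with the package
# internals beyond the clamp definition)
brute_second_binding <- function(La, L1, x1, L2, c) {
  clamp <- function(v) min(max(v, 0), L2)
  N1 <- 0
  N2 <- 0
  for (x in 0:(La - L2)) {
    if (((x + L2) < x1) || (x > (x1 + L1))) {
      N1 <- N1 + 2
    } else if (x < x1 && (x + L2) > x1) {
      N2 <- N2 + clamp(x1 - x) + c * clamp(L2 - (x1 - x))
    } else if (x >= x1 && x < (x1 + L1)) {
      N2 <- N2 + clamp(L2 - ((x1 + L1) - x)) + c * clamp((x1 + L1) - x)
    }
  }
  list(N1 = N1, N2 = N2, p2 = if (N1 + N2 > 0) N2 / (N1 + N2) else NA_real_)
}

# stationary weight of a two-row configuration (detailed-balance law)
config_weight <- function(occ, K, w, c) {
  n <- sum(occ)
  p_row <- sum(occ[1, -1] * occ[1, -ncol(occ)]) +
    sum(occ[2, -1] * occ[2, -ncol(occ)])
  p_cross <- sum(occ[1, ] * occ[2, ])
  K^n * (w^2)^p_row * (c^2)^p_cross
}

# Rayleigh CDF of the first-binding time, a = kon_len * v_grow
first_binding_cdf <- function(t, a) 1 - exp(-a * t^2 / 2)

# CDF of the bound-site age: integral of sqrt(pi a / 2) erfc(tau sqrt(a/2)),
# using  int_0^y erfc(u) du = y erfc(y) + (1 - exp(-y^2)) / sqrt(pi)
site_age_cdf <- function(tau, a) {
  y <- tau * sqrt(a / 2)
  erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)
  sqrt(pi) * y * erfc(y) + 1 - exp(-y^2)
}

# total propensity of a state, from the exported local rate functions
total_propensity <- function(state, params) {
  tot <- 0
  for (j in 1:2) for (i in seq_len(state$N)) {
    tot <- tot + if (state$occupancy[j, i] == 1L)
      local_off_rate(state, params, i, j)
    else local_on_rate(state, params, i, j)
  }
  tot + if (params$deterministic_growth) 0 else params$v_grow
}

make_kymograph <- function(intensity, frame_interval = 1,
                           site_length_nm = 21.6) {
  structure(
    list(intensity = intensity,
         frame_times = seq_len(nrow(intensity)) * frame_interval,
         site_length_nm = site_length_nm),
    class = "kymograph"
  )
}
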