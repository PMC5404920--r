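# Exact equilibrium of the fixed-length two-row lattice.
#
# The kinetic rules (on-rate multiplied by w per occupied same-row
# neighbour and by c for an occupied opposite site; off-rate divided by
# the same factors) satisfy detailed balance with respect to
#
#   pi(config) ~ K^n * (w^2)^p_row * (c^2)^p_cross
#
# where K = k_on/k_off, n = occupied sites, p_row = same-row adjacent
# occupied pairs and p_cross = occupied opposite-site pairs.  The squares
# arise because each factor acts on the on-rate *and* its inverse on the
# off-rate, so the equilibrium constant of a site gains the factor twice.
# This is a two-row Ising chain in a field; with open boundaries its
# partition function follows from a 4x4 column-transfer matrix (the four
# joint occupancies of one site pair).

#' Specification of an equilibrium lattice
#'
#' @param K Per-site equilibrium constant `k_on / k_off` (> 0).
#' @param w,c Cooperativity factors (as in [lattice_params()]).
#' @param N Site count (integer >= 1) or `Inf` for the thermodynamic
#'   limit.
#' @return An `equilibrium_spec` object.
#' @export
equilibrium_spec <- function(K, w = 1, c = 1, N = Inf) {
  stopifnot(is.numeric(K), K > 0, w >= 0, c >= 0,
            (is.infinite(N) || (N >= 1 && N == as.integer(N))))
  structure(list(K = K, w = w, c = c, N = N), class = "equilibrium_spec")
}

# column states: 1 = (0,0), 2 = (1,0), 3 = (0,1), 4 = (1,1)
col_occ <- c(0L, 1L, 1L, 2L)
col_rows <- rbind(c(0L, 1L, 0L, 1L),   # row 1 occupancy per state
                  c(0L, 0L, 1L, 1L))   # row 2 occupancy per state

col_weight <- function(spec) spec$K^col_occ * ifelse(col_occ == 2L, spec$c^2, 1)

edge_weight_matrix <- function(spec) {
  # w^2 per same-row occupied adjacency between consecutive columns
  E <- matrix(1, 4, 4)
  for (s in 1:4) for (sp in 1:4) {
    adj <- col_rows[1, s] * col_rows[1, sp] + col_rows[2, s] * col_rows[2, sp]
    E[s, sp] <- spec$w^(2 * adj)
  }
  E
}

#' Exact coverage by configuration enumeration
#'
#' Brute-force sum over all `2^(2N)` configurations of the stationary law
#' `pi ~ K^n (w^2)^p_row (c^2)^p_cross`.  Exponential in N; refuse beyond
#' N = 10 and use [transfer_matrix_coverage()] instead.
#'
#' @param spec An [equilibrium_spec()] with finite `N <= 10`.
#' @return A tibble with `coverage` (mean per-site occupancy),
#'   `single_fraction` and `double_fraction` (fractions of columns with
#'   exactly one / both grooves occupied).
#' @export
#' @examples
#' enumerate_equilibrium(equilibrium_spec(K = 1, N = 3))$coverage  # 0.5
enumerate_equilibrium <- function(spec) {
  stopifnot(inherits(spec, "equilibrium_spec"))
  N <- spec$N
  if (is.infinite(N)) abort("enumeration needs finite N")
  if (N > 10)
    abort("N too large for 4^N enumeration; use transfer_matrix_coverage()")
  m <- col_weight(spec)
  states <- rep(list(1:4), N)
  grid <- as.matrix(expand.grid(states))
  Z <- 0; occ_sum <- 0; single_sum <- 0; double_sum <- 0
  for (r in seq_len(nrow(grid))) {
    s <- grid[r, ]
    wgt <- prod(m[s])
    if (N > 1) {
      for (k in seq_len(N - 1)) {
        adj <- col_rows[1, s[k]] * col_rows[1, s[k + 1]] +
               col_rows[2, s[k]] * col_rows[2, s[k + 1]]
        wgt <- wgt * spec$w^(2 * adj)
      }
    }
    Z <- Z + wgt
    occ_sum <- occ_sum + wgt * sum(col_occ[s])
    single_sum <- single_sum + wgt * sum(col_occ[s] == 1L)
    double_sum <- double_sum + wgt * sum(col_occ[s] == 2L)
  }
  tibble::tibble(
    coverage = occ_sum / (2 * N * Z),
    single_fraction = single_sum / (N * Z),
    double_fraction = double_sum / (N * Z)
  )
}

#' Exact coverage from the 4x4 transfer matrix
#'
#' For finite `N`, propagates open-boundary transfer-matrix products
#' exactly (with running occupancy accumulators, so no numerical
#' differentiation is involved).  For `N = Inf`, uses the dominant
#' eigenvalue of the transfer matrix and its left/right eigenvectors: the
#' stationary column-state distribution is `l(s) r(s) / sum(l r)`.
#'
#' @param spec An [equilibrium_spec()].
#' @return A tibble as in [enumerate_equilibrium()].
#' @export
#' @examples
#' transfer_matrix_coverage(equilibrium_spec(K = 2, N = Inf))$coverage  # 2/3
transfer_matrix_coverage <- function(spec) {
  stopifnot(inherits(spec, "equilibrium_spec"))
  m <- col_weight(spec)
  E <- edge_weight_matrix(spec)
  if (is.finite(spec$N)) {
    N <- spec$N
    # a[s]: partition sum of the first k columns ending in state s
    # b*, accumulators of (weight * statistic) for occupancy, single, double
    a <- m
    b_occ <- m * col_occ
    b_sgl <- m * (col_occ == 1L)
    b_dbl <- m * (col_occ == 2L)
    if (N > 1) {
      for (k in 2:N) {
        Tm <- E * rep(m, each = 4)      # T[s, sp] = E[s, sp] * m[sp]
        a_new <- as.vector(a %*% Tm)
        b_occ <- as.vector(b_occ %*% Tm) + a_new * col_occ
        b_sgl <- as.vector(b_sgl %*% Tm) + a_new * (col_occ == 1L)
        b_dbl <- as.vector(b_dbl %*% Tm) + a_new * (col_occ == 2L)
        a <- a_new
        # rescale to avoid overflow; ratios are what we report
        sc <- sum(a)
        if (sc > 1e100 || sc < 1e-100) {
          a <- a / sc; b_occ <- b_occ / sc; b_sgl <- b_sgl / sc
          b_dbl <- b_dbl / sc
        }
      }
    }
    Z <- sum(a)
    return(tibble::tibble(
      coverage = sum(b_occ) / (2 * N * Z),
      single_fraction = sum(b_sgl) / (N * Z),
      double_fraction = sum(b_dbl) / (N * Z)
    ))
  }
  Tm <- E * rep(m, each = 4)
  er <- eigen(Tm)
  el <- eigen(t(Tm))
  ir <- which.max(abs(er$values))
  il <- which.max(abs(el$values))
  if (abs(Re(er$values[ir])) - max(abs(er$values[-ir])) <
      1e-12 * abs(Re(er$values[ir])) && spec$w > 0)
    warn("near-degenerate dominant eigenvalue; coverage may be ill-conditioned")
  r <- Re(er$vectors[, ir]); l <- Re(el$vectors[, il])
  p <- l * r / sum(l * r)
  if (any(p < -1e-10)) p <- abs(p) / sum(abs(p))
  tibble::tibble(
    coverage = sum(p * col_occ) / 2,
    single_fraction = sum(p * (col_occ == 1L)),
    double_fraction = sum(p * (col_occ == 2L))
  )
}

# midpoint of the equilibrium coverage transition in K, by bisection
equilibrium_midpoint_K <- function(w = 1, c = 1, N = Inf,
                                   lower = 1e-12, upper = 1e6) {
  f <- function(K)
    transfer_matrix_coverage(equilibrium_spec(K, w, c, N))$coverage - 0.5
  stats::uniroot(f, lower = lower, upper = upper, tol = 1e-12)$root
}
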