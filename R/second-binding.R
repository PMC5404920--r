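# Counting model for where a second tropomyosin cable lands relative to
# the first.  The filament is a grid of 100 nm units (the optical
# resolution): length La, first cable of length L1 starting at x1, second
# cable of length L2.  N1 counts placements completely clear of the first
# cable (doubled, because both grooves are free there); N2 is a weighted
# sum over overlapping placements in which each overlapping unit carries
# the indirect-cooperativity weight c and each non-overlapping unit
# weight 1, with each term clamped to [0, L2] exactly as in the counting
# rules.  The overlap probability is p2 = N2 / (N1 + N2).

#' Construct/validate second-binding geometries
#'
#' @param data A data frame with integer columns `La` (filament length),
#'   `L1` (first-cable length), `x1` (first-cable start, 0-based), `L2`
#'   (second-cable length), all in 100-nm grid units, and optionally
#'   `overlapped` (logical observed outcome).
#' @return The validated tibble (invisibly classed
#'   `second_binding_events`).
#' @export
second_binding_events <- function(data) {
  data <- tibble::as_tibble(data)
  req <- c("La", "L1", "x1", "L2")
  miss <- setdiff(req, names(data))
  if (length(miss))
    abort(paste("missing columns:", paste(miss, collapse = ", ")))
  bad <- which(
    data$La < 1 | data$L1 < 1 | data$L2 < 1 | data$x1 < 0 |
      data$x1 + data$L1 > data$La | data$L2 > data$La |
      data$La != round(data$La) | data$L1 != round(data$L1) |
      data$x1 != round(data$x1) | data$L2 != round(data$L2)
  )
  if (length(bad))
    abort(sprintf("invalid geometry in row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  data
}

clamp_L2 <- function(x, L2) pmin(pmax(x, 0), L2)

count_geom_parts <- function(La, L1, x1, L2, strict = TRUE) {
  # N2 is linear in c: N2(c) = A + c * B, because each clamped term is
  # independent of c.  Returning the parts lets likelihood grids over c be
  # evaluated without re-counting.
  xs <- 0:(La - L2)
  clear <- if (strict) ((xs + L2) < x1) | (xs > (x1 + L1))
           else ((xs + L2) <= x1) | (xs >= (x1 + L1))
  N1 <- 2 * sum(clear)
  left <- (xs < x1) & ((xs + L2) > x1)
  right <- (xs >= x1) & (xs < (x1 + L1))
  A <- sum(clamp_L2(x1 - xs[left], L2)) +
    sum(clamp_L2(L2 - ((x1 + L1) - xs[right]), L2))
  B <- sum(clamp_L2(L2 - (x1 - xs[left]), L2)) +
    sum(clamp_L2((x1 + L1) - xs[right], L2))
  c(N1 = N1, A = A, B = B)
}

count_geom <- function(La, L1, x1, L2, c) {
  p <- count_geom_parts(La, L1, x1, L2, strict = TRUE)
  c(N1 = unname(p["N1"]), N2 = unname(p["A"] + c * p["B"]))
}

count_geom_inclusive <- function(La, L1, x1, L2, c) {
  # sensitivity variant: placements that merely touch the first cable
  # count as clear (non-strict inequalities in N1)
  p <- count_geom_parts(La, L1, x1, L2, strict = FALSE)
  c(N1 = unname(p["N1"]), N2 = unname(p["A"] + c * p["B"]))
}

#' Placement counts and overlap probability
#'
#' `count_nonoverlap()` returns N1, `count_overlap_weighted()` returns N2
#' for a single geometry; `overlap_probability()` is the data-frame verb
#' that appends `N1`, `N2` and `p2 = N2 / (N1 + N2)` to a table of
#' geometries.
#'
#' @param La,L1,x1,L2 Geometry in 100-nm grid units (see
#'   [second_binding_events()]).
#' @param c Indirect cooperativity factor (> 0; overlapping units are
#'   weighted by `c`).
#' @param inclusive_ends If `TRUE`, placements that merely touch the
#'   first cable count as clear in N1 (sensitivity variant; the default
#'   `FALSE` uses the strict inequalities of the counting rules, under
#'   which touching placements enter neither count).
#' @return Counts, or (for `overlap_probability`) the input tibble with
#'   columns `N1`, `N2`, `p2` added.
#' @export
#' @examples
#' count_nonoverlap(La = 10, L1 = 2, x1 = 4, L2 = 2)            # 8
#' count_overlap_weighted(La = 10, L1 = 2, x1 = 4, L2 = 2, c = 1) # 6
count_nonoverlap <- function(La, L1, x1, L2, inclusive_ends = FALSE) {
  g <- second_binding_events(tibble::tibble(La = La, L1 = L1, x1 = x1, L2 = L2))
  f <- if (inclusive_ends) count_geom_inclusive else count_geom
  unname(f(g$La, g$L1, g$x1, g$L2, c = 1)["N1"])
}

#' @rdname count_nonoverlap
#' @export
count_overlap_weighted <- function(La, L1, x1, L2, c, inclusive_ends = FALSE) {
  stopifnot(c > 0)
  g <- second_binding_events(tibble::tibble(La = La, L1 = L1, x1 = x1, L2 = L2))
  f <- if (inclusive_ends) count_geom_inclusive else count_geom
  unname(f(g$La, g$L1, g$x1, g$L2, c = c)["N2"])
}

#' @rdname count_nonoverlap
#' @param data A geometry table (see [second_binding_events()]).
#' @export
overlap_probability <- function(data, c = 1, inclusive_ends = FALSE) {
  stopifnot(c > 0)
  data <- second_binding_events(data)
  f <- if (inclusive_ends) count_geom_inclusive else count_geom
  counts <- purrr::pmap(list(data$La, data$L1, data$x1, data$L2),
                        function(La, L1, x1, L2) f(La, L1, x1, L2, c = c))
  data$N1 <- vapply(counts, `[[`, numeric(1), "N1")
  data$N2 <- vapply(counts, `[[`, numeric(1), "N2")
  if (any(data$N1 + data$N2 == 0))
    abort("degenerate geometry: N1 + N2 = 0 (no admissible placement)")
  data$p2 <- data$N2 / (data$N1 + data$N2)
  data
}

#' Bin events by current occupancy
#'
#' The current occupancy when the second cable lands is
#' `L1 / (2 * La)` (the first cable covers at most one of the two
#' grooves, so occupancy cannot exceed 50%).  Bins are half-open at the
#' interior edges: [0, 12.5%), [12.5%, 25%), [25%, 50%].
#'
#' @inheritParams overlap_probability
#' @return The tibble with `occupancy` and an ordered factor
#'   `occupancy_bin` added.
#' @export
bin_by_occupancy <- function(data) {
  data <- second_binding_events(data)
  occ <- data$L1 / (2 * data$La)
  if (any(occ > 0.5)) abort("initial occupancy cannot exceed 50%")
  labs <- c("0-12.5%", "12.5-25%", "25-50%")
  data$occupancy <- occ
  data$occupancy_bin <- factor(
    ifelse(occ < 0.125, labs[1], ifelse(occ < 0.25, labs[2], labs[3])),
    levels = labs, ordered = TRUE
  )
  data
}

#' Bootstrap the per-bin overlap fractions
#'
#' Re-performs the observed set of second-binding experiments `n_boot`
#' times under a chosen indirect cooperativity `c`: for every event an
#' overlap outcome is drawn Bernoulli(p2), and the overlap fraction is
#' computed per occupancy bin.  Bins with no events are absent from the
#' output (not reported as zero).
#'
#' @inheritParams overlap_probability
#' @param n_boot Number of bootstrap replicates (default 5000).
#' @return A `bootstrap_result` tibble: per bin, the number of events,
#'   the mean and SD of the replicate overlap fractions, plus `c` and
#'   `n_boot`.
#' @export
bootstrap_binned_fractions <- function(data, c = 1, n_boot = 5000) {
  data <- bin_by_occupancy(overlap_probability(data, c = c))
  out <- purrr::map_dfr(levels(data$occupancy_bin), function(b) {
    sub <- data[data$occupancy_bin == b, ]
    if (nrow(sub) == 0) return(NULL)
    draws <- matrix(rbinom(n_boot * nrow(sub), 1, rep(sub$p2, each = n_boot)),
                    nrow = n_boot)
    frac <- rowMeans(draws)
    tibble::tibble(occupancy_bin = b, n_events = nrow(sub),
                   mean_fraction = mean(frac), sd_fraction = sd(frac),
                   mean_p2 = mean(sub$p2))
  })
  out$c <- c
  out$n_boot <- n_boot
  structure(out, class = c("bootstrap_result", class(out)))
}

#' Estimate the indirect cooperativity factor from observed outcomes
#'
#' Profile likelihood over a log-spaced grid of `c`: each event
#' contributes `y * log(p2(c)) + (1 - y) * log(1 - p2(c))` with `y` the
#' observed overlap flag.  The CI is a nonparametric bootstrap over
#' events; a likelihood-ratio test against `c = 1` (no indirect
#' cooperativity) is included.
#'
#' @param data A geometry table with a logical `overlapped` column.
#' @param c_grid Grid of candidate `c` values.
#' @param n_boot Bootstrap replicates for the CI.
#' @param conf_level Confidence level.
#' @return A `c_estimate` object; see [tidy()] and [glance()].
#' @export
estimate_c <- function(data, c_grid = exp(seq(log(0.05), log(20), length.out = 201)),
                       n_boot = 200, conf_level = 0.95) {
  data <- second_binding_events(data)
  if (!"overlapped" %in% names(data))
    abort("estimate_c() needs an `overlapped` column of observed outcomes")
  if (nrow(data) < 10)
    warn("fewer than 10 events; the estimate of c will be weak")
  y <- as.logical(data$overlapped)
  if (all(y) || all(!y))
    warn("all outcomes identical; the likelihood for c may be degenerate")
  parts <- t(mapply(count_geom_parts, data$La, data$L1, data$x1, data$L2))
  # p2(c) = (A + cB) / (N1 + A + cB); profile the Bernoulli likelihood
  loglik_vec <- function(cc, idx) {
    N1 <- parts[idx, "N1"]; A <- parts[idx, "A"]; B <- parts[idx, "B"]
    yy <- y[idx]
    vapply(cc, function(ci) {
      n2 <- A + ci * B
      p2 <- pmin(pmax(n2 / (N1 + n2), 1e-12), 1 - 1e-12)
      sum(ifelse(yy, log(p2), log(1 - p2)))
    }, numeric(1))
  }
  all_idx <- seq_len(nrow(data))
  ll <- loglik_vec(c_grid, all_idx)
  c_hat <- c_grid[which.max(ll)]
  ll_1 <- loglik_vec(1, all_idx)
  lr_stat <- 2 * (max(ll) - ll_1)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(nrow(data), replace = TRUE)
    llb <- loglik_vec(c_grid, i)
    c_grid[which.max(llb)]
  }, numeric(1))
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- quantile(boot, probs, names = FALSE)
  structure(
    list(c_hat = c_hat, conf_low = ci[1], conf_high = ci[2],
         conf_level = conf_level, loglik = max(ll), loglik_c1 = ll_1,
         lr_stat = lr_stat, p_value_c1 = pchisq(lr_stat, 1, lower.tail = FALSE),
         n = nrow(data), grid = tibble::tibble(c = c_grid, loglik = ll)),
    class = "c_estimate"
  )
}

#' @export
print.c_estimate <- function(x, ...) {
  cat(sprintf(
    "<c_estimate> c = %.3g (%.0f%% CI %.3g-%.3g), n = %d; LR vs c=1: p = %.3g\n",
    x$c_hat, 100 * x$conf_level, x$conf_low, x$conf_high, x$n, x$p_value_c1))
  invisible(x)
}

#' @export
tidy.c_estimate <- function(x, ...) {
  tibble::tibble(term = "c", estimate = x$c_hat,
                 conf.low = x$conf_low, conf.high = x$conf_high)
}

#' @export
glance.c_estimate <- function(x, ...) {
  tibble::tibble(c_hat = x$c_hat, logLik = x$loglik,
                 lr_stat_c1 = x$lr_stat, p_value_c1 = x$p_value_c1,
                 nobs = x$n)
}
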