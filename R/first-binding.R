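# Time and position of the first tropomyosin binding event on a growing
# filament.  With a length-proportional association rate k_on (per nm) and
# a filament growing at v_grow (nm/s), the unbound-survival probability is
# P1(t) = exp(-a t^2 / 2) with a = k_on * v_grow, the first-binding time
# is Rayleigh-distributed, P(tau) = a tau exp(-a tau^2 / 2), and the age
# of the bound site follows an erfc law.  A discrete-time Monte Carlo twin
# mirrors the analytic results and supplies finite-sample noise.

#' Parameters of the first-binding model
#'
#' @param kon_len Association rate per unit filament length
#'   (s^-1 nm^-1).  4e-6 s^-1 nm^-1 reproduces the measured first-binding
#'   times at the Hill-midpoint tropomyosin concentration.
#' @param v_grow Filament growth rate in nm/s (> 0).
#' @param dt Monte Carlo time step in seconds; `NULL` picks
#'   `0.02 / sqrt(kon_len * v_grow)` (2% of the modal binding time), small
#'   enough that the per-step binding probability stays below 0.1 over
#'   essentially the whole binding-time distribution.
#' @param max_time Censoring horizon for the simulation (s).
#' @param seed Optional RNG seed.
#' @return A `first_binding_params` object.
#' @export
first_binding_params <- function(kon_len = 4e-6, v_grow = 47.5, dt = NULL,
                                 max_time = 2000, seed = NULL) {
  stopifnot(kon_len >= 0, v_grow > 0, max_time > 0)
  a <- kon_len * v_grow
  dt_auto <- if (a > 0) 0.02 / sqrt(a) else max_time / 1000
  if (is.null(dt)) dt <- dt_auto
  stopifnot(dt > 0)
  # discretisation check at the 99.9% quantile of the binding time
  t_tail <- if (a > 0) min(sqrt(2 * log(1000) / a), max_time) else max_time
  if (a > 0 && 1 - exp(-a * t_tail * dt) > 0.1)
    warn("dt is coarse: per-step binding probability exceeds 0.1 in the upper tail")
  structure(list(kon_len = kon_len, v_grow = v_grow, dt = dt,
                 max_time = max_time, seed = seed, a = a),
            class = "first_binding_params")
}

#' Analytic first-binding laws
#'
#' `survival_probability()` is the probability that no binding has
#' occurred by time `t`; `first_binding_pdf()` the density of the first
#' binding time (Rayleigh); `site_age_pdf()` the density of the age of
#' the site where binding occurs,
#' `sqrt(pi a / 2) * erfc(tau * sqrt(a / 2))` with `a = kon_len * v_grow`.
#'
#' @param t,tau,tau_age Times in seconds (vectorised, >= 0).
#' @param params A [first_binding_params()].
#' @return Probabilities or densities (s^-1).
#' @export
#' @examples
#' p <- first_binding_params()
#' survival_probability(0, p)  # 1
survival_probability <- function(t, params) {
  stopifnot(all(t >= 0))
  exp(-params$a * t^2 / 2)
}

#' @rdname survival_probability
#' @export
first_binding_pdf <- function(tau, params) {
  stopifnot(all(tau >= 0))
  params$a * tau * exp(-params$a * tau^2 / 2)
}

#' @rdname survival_probability
#' @export
site_age_pdf <- function(tau_age, params) {
  stopifnot(all(tau_age >= 0))
  sqrt(pi * params$a / 2) * erfc(tau_age * sqrt(params$a / 2))
}

# complementary error function via the normal CDF
erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)

#' Simulate first-binding events (discrete-time Monte Carlo)
#'
#' Steps time by `dt`; at each step the filament has length
#' `v_grow * t` and binding occurs with probability
#' `1 - exp(-kon_len * v_grow * t * dt)`.  On binding, the position is
#' uniform along the filament, measured from the barbed (growing) end,
#' and the site age is `position / v_grow`.  Events not bound by
#' `max_time` are returned censored.
#'
#' @param params A [first_binding_params()].
#' @param n Number of independent filaments.
#' @return A tibble with columns `t_bind`, `position_nm` (from the barbed
#'   end), `age_s`, `filament_length_nm` and `censored`.
#' @export
simulate_first_binding <- function(params, n = 1) {
  stopifnot(inherits(params, "first_binding_params"), n >= 0)
  if (!is.null(params$seed)) set.seed(params$seed)
  if (n == 0)
    return(tibble::tibble(t_bind = numeric(), position_nm = numeric(),
                          age_s = numeric(), filament_length_nm = numeric(),
                          censored = logical()))
  dt <- params$dt
  a <- params$a
  t_bind <- rep(NA_real_, n)
  alive <- seq_len(n)
  t <- 0
  while (length(alive) > 0 && t < params$max_time) {
    t <- t + dt
    p <- 1 - exp(-a * t * dt)
    hit <- runif(length(alive)) < p
    t_bind[alive[hit]] <- t
    alive <- alive[!hit]
  }
  censored <- is.na(t_bind)
  t_out <- ifelse(censored, params$max_time, t_bind)
  len <- params$v_grow * t_out
  pos <- ifelse(censored, NA_real_, runif(n) * len)
  tibble::tibble(
    t_bind = t_out,
    position_nm = pos,
    age_s = pos / params$v_grow,
    filament_length_nm = len,
    censored = censored
  )
}

#' Convert a barbed-end position to a pointed-end position
#'
#' Simulated positions are measured from the barbed (growing) end;
#' experimental tables often measure from the photobleached pointed end.
#'
#' @param position_nm Distance from the barbed end (nm).
#' @param filament_length_nm Filament length at binding (nm).
#' @return Distance from the pointed end (nm).
#' @export
position_from_pointed <- function(position_nm, filament_length_nm) {
  filament_length_nm - position_nm
}

#' Maximum-likelihood fit of the per-length association rate
#'
#' Under the Rayleigh first-binding law the MLE of `a = kon_len * v_grow`
#' with right-censoring is `a_hat = 2 * n_uncensored / sum(tau^2)` where
#' the sum runs over all times (censored times enter through the survival
#' term only).  A nonparametric bootstrap over events gives the CI.
#'
#' @param data A tibble with columns `t_bind` and `censored` (as from
#'   [simulate_first_binding()]), or a numeric vector of uncensored
#'   binding times.
#' @param v_grow Filament growth rate in nm/s used to convert `a` to a
#'   per-length rate.
#' @param n_boot Bootstrap replicates for the CI.
#' @param conf_level Confidence level.
#' @return A `kon_fit` object; see [tidy()] and [glance()].
#' @export
fit_kon <- function(data, v_grow, n_boot = 200, conf_level = 0.95) {
  if (is.numeric(data))
    data <- tibble::tibble(t_bind = data, censored = FALSE)
  stopifnot(all(c("t_bind", "censored") %in% names(data)), v_grow > 0)
  n_unc <- sum(!data$censored)
  if (n_unc == 0) abort("all events are censored; kon is not identifiable")
  if (n_unc < 2 && nrow(data) < 2)
    warn("fewer than 2 events; the estimate is unstable")
  a_hat_of <- function(d) 2 * sum(!d$censored) / sum(d$t_bind^2)
  a_hat <- a_hat_of(data)
  boot <- vapply(seq_len(n_boot), function(b) {
    d <- data[sample.int(nrow(data), replace = TRUE), ]
    if (sum(!d$censored) == 0) return(NA_real_)
    a_hat_of(d)
  }, numeric(1))
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- quantile(boot / v_grow, probs, na.rm = TRUE, names = FALSE)
  structure(
    list(kon_len = a_hat / v_grow, a = a_hat, v_grow = v_grow,
         conf_low = ci[1], conf_high = ci[2], conf_level = conf_level,
         n = nrow(data), n_uncensored = n_unc, n_boot = n_boot),
    class = "kon_fit"
  )
}

#' @export
print.kon_fit <- function(x, ...) {
  cat(sprintf(
    "<kon_fit> kon = %.3g /s/nm (%.0f%% CI %.3g-%.3g), n = %d (%d uncensored)\n",
    x$kon_len, 100 * x$conf_level, x$conf_low, x$conf_high, x$n,
    x$n_uncensored))
  invisible(x)
}

#' @export
tidy.kon_fit <- function(x, ...) {
  tibble::tibble(term = "kon_len", estimate = x$kon_len,
                 conf.low = x$conf_low, conf.high = x$conf_high)
}

#' @export
glance.kon_fit <- function(x, ...) {
  tibble::tibble(kon_len = x$kon_len, a = x$a, v_grow = x$v_grow,
                 nobs = x$n, n_uncensored = x$n_uncensored)
}
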