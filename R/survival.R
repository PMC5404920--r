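# Residence-time analysis for single bound molecules: Kaplan-Meier
# product-limit estimation with right-censoring, and a single-exponential
# fit f(x) = f0 * exp(-x / T1) giving the residence time T1 and
# k_off = 1 / T1.

#' Kaplan-Meier survival curve of residence times
#'
#' Product-limit estimator on right-censored dwell times.  At tied times
#' the standard convention applies (events processed before censorings);
#' the curve starts at S = 1.  Computation goes through
#' [survival::survfit()].
#'
#' @param data A tibble with columns `duration_s` (> 0) and `censored`
#'   (logical: `TRUE` if the molecule was still bound when observation
#'   ended).
#' @return A `km_curve` tibble: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
#' @examples
#' km <- kaplan_meier(tibble::tibble(duration_s = c(1, 2, 3),
#'                                   censored = c(FALSE, TRUE, FALSE)))
kaplan_meier <- function(data) {
  stopifnot(all(c("duration_s", "censored") %in% names(data)))
  if (any(data$duration_s <= 0)) abort("durations must be positive")
  if (all(data$censored)) abort("all events censored; no curve can be estimated")
  fit <- survival::survfit(
    survival::Surv(data$duration_s, !data$censored) ~ 1,
    conf.type = "none"
  )
  out <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
  structure(out, class = c("km_curve", class(out)))
}

#' Single-exponential fit of residence times
#'
#' Default mode `"km-curve"` performs nonlinear least squares of
#' `f0 * exp(-x / T1)` to the Kaplan-Meier curve (the point (0, 1) is
#' included).  Mode `"mle"` is the censored maximum-likelihood
#' alternative, `T1 = sum(durations) / n_uncensored` with `f0 = 1`,
#' which is better behaved under heavy censoring.
#'
#' @param data A residence-time tibble (`duration_s`, `censored`) or a
#'   `km_curve` (km-curve mode only).
#' @param mode `"km-curve"` or `"mle"`.
#' @return An `exp_fit` with fields `f0`, `T1` (s), `k_off` (= 1/T1,
#'   s^-1); see [tidy()] and [glance()].
#' @export
fit_exponential <- function(data, mode = c("km-curve", "mle")) {
  mode <- match.arg(mode)
  if (mode == "mle") {
    stopifnot(all(c("duration_s", "censored") %in% names(data)))
    n_unc <- sum(!data$censored)
    if (n_unc == 0) abort("all events censored; T1 is not identifiable")
    T1 <- sum(data$duration_s) / n_unc
    return(new_exp_fit(f0 = 1, T1 = T1, mode = mode, n = nrow(data)))
  }
  km <- if (inherits(data, "km_curve")) data else kaplan_meier(data)
  if (length(unique(km$time)) < 3)
    abort("need at least 3 distinct time points on the curve")
  df <- tibble::tibble(x = c(0, km$time), y = c(1, km$survival))
  # initialiser: log-linear regression on the positive part of the curve
  pos <- df$y > 0
  init <- lm(log(y) ~ x, data = df[pos, ])
  T1_0 <- -1 / min(coef(init)[["x"]], -1e-12)
  f0_0 <- exp(coef(init)[["(Intercept)"]])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ f0 * exp(-x / T1), data = df,
                      start = list(f0 = f0_0, T1 = T1_0),
                      lower = c(1e-8, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(sprintf(
      "exponential fit did not converge (start f0 = %.3g, T1 = %.3g): %s",
      f0_0, T1_0, conditionMessage(e)))
  )
  cf <- coef(fit)
  new_exp_fit(f0 = cf[["f0"]], T1 = cf[["T1"]], mode = mode,
              n = nrow(km), rss = sum(stats::resid(fit)^2))
}

new_exp_fit <- function(f0, T1, mode, n, rss = NA_real_) {
  structure(list(f0 = f0, T1 = T1, k_off = 1 / T1, mode = mode,
                 n = n, rss = rss),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit (%s)> f0 = %.4g, T1 = %.4g s, k_off = %.4g /s\n",
              x$mode, x$f0, x$T1, x$k_off))
  invisible(x)
}

#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = c("f0", "T1", "k_off"),
                 estimate = c(x$f0, x$T1, x$k_off))
}

#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(f0 = x$f0, T1 = x$T1, k_off = x$k_off, mode = x$mode,
                 nobs = x$n, rss = x$rss)
}

#' Residence times of molecules in a simulated coated cable
#'
#' Extracts per-molecule dwell times (bind to unbind of the same
#' molecule) from a lattice trajectory's event log, optionally keeping
#' only interior sites (away from the filament ends), and flags molecules
#' still bound at the end of the run as censored.  In a fully coated
#' cable these dwell times are exponential with the effective rate
#' `k_off / (w^2 * c)` - the measured single-molecule off-rate
#' corresponding to the model's microscopic `k_off`.
#'
#' @param trajectory A `lattice_trajectory` with an event log.
#' @param interior_margin Exclude binding events within this many sites
#'   of either filament end.
#' @return A residence-time tibble (`duration_s`, `censored`, plus
#'   `site`, `row`).
#' @export
residence_times_from_trajectory <- function(trajectory, interior_margin = 1) {
  ev <- trajectory$events
  if (is.null(ev)) abort("trajectory has no event log")
  N <- trajectory$final_state$N
  t_end <- trajectory$final_state$t
  binds <- ev[ev$event == "bind", ]
  unbinds <- ev[ev$event == "unbind", ]
  off_time <- setNames(unbinds$time, unbinds$molecule)
  keep <- binds$site > interior_margin & binds$site <= N - interior_margin
  binds <- binds[keep, ]
  t_off <- off_time[as.character(binds$molecule)]
  censored <- is.na(t_off)
  tibble::tibble(
    duration_s = ifelse(censored, t_end - binds$time, t_off - binds$time),
    censored = censored,
    site = binds$site, row = binds$row
  )
}
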