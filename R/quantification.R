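# Concentration-response quantification: free-tropomyosin correction,
# Hill-equation fitting, and severing-rate arithmetic.

#' Free tropomyosin concentration
#'
#' Corrects the added concentration for the bound pool:
#' `([added] - f_actin * occupancy / ratio) * 0.001`, returning uM.  The
#' defaults are a 250 nM F-actin reference and a 1:4 bound-tropomyosin :
#' F-actin stoichiometry (one dimer spans four monomers of one strand).
#'
#' @param added_nM Added tropomyosin concentration (nM), vectorised.
#' @param occupancy Total occupancy in [0, 1].
#' @param f_actin_nM F-actin concentration (nM).
#' @param ratio Bound tropomyosin : F-actin stoichiometric ratio.
#' @return Free concentration in uM.
#' @export
#' @examples
#' free_concentration(2000, 0.98)  # 1.93875
free_concentration <- function(added_nM, occupancy, f_actin_nM = 250,
                               ratio = 4) {
  stopifnot(all(added_nM >= 0), all(occupancy >= 0), all(occupancy <= 1),
            f_actin_nM >= 0, ratio > 0)
  out <- (added_nM - f_actin_nM * occupancy / ratio) * 0.001
  if (any(out < 0))
    abort("negative free concentration: bound pool exceeds added (over-saturated inputs)")
  out
}

#' Fit a Hill equation to an occupancy curve
#'
#' Fits `theta = [L]^n / (K_d + [L]^n)` by nonlinear least squares.  Note
#' that in this form `K_d` carries units of `[L]^n`; the half-maximal
#' concentration `EC50 = K_d^(1/n)` is reported alongside.  Internally the
#' curve is parameterised as a logistic in `log [L]` (with parameters
#' `log EC50` and `n`), which is numerically well-behaved even for very
#' steep curves; the initialiser is a logit-log regression.  With
#' `amplitude = "free"` a multiplicative plateau `A` is also fitted, for
#' curves that saturate below 1.
#'
#' @param data A data frame with the concentration and occupancy columns.
#' @param concentration,occupancy Column names (as strings).
#' @param amplitude `"fixed"` (plateau 1, the printed form) or `"free"`.
#' @return A `hill_fit` with `K_d`, `n`, `ec50` (and `A` if free); see
#'   [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' d <- tibble::tibble(concentration = 2^seq(-2, 2, length.out = 9))
#' d$occupancy <- d$concentration^3 / (1.5^3 + d$concentration^3)
#' fit_hill(d)
fit_hill <- function(data, concentration = "concentration",
                     occupancy = "occupancy",
                     amplitude = c("fixed", "free")) {
  amplitude <- match.arg(amplitude)
  L <- data[[concentration]]
  th <- data[[occupancy]]
  if (is.null(L) || is.null(th))
    abort("concentration/occupancy columns not found")
  keep <- is.finite(L) & is.finite(th) & L > 0
  L <- L[keep]; th <- th[keep]
  if (length(L) < 3) abort("need at least 3 points with positive concentration")
  top <- if (amplitude == "free") max(th) else 1
  if (!any(th < 0.5 * top) || !any(th > 0.5 * top))
    abort("data do not span the half-maximal occupancy; the fit is unconstrained")
  # initialiser: logit-log regression on the interior points
  eps <- 1e-4
  th_c <- pmin(pmax(th / max(top, 1e-12), eps), 1 - eps)
  init <- lm(log(th_c / (1 - th_c)) ~ log(L))
  n0 <- max(coef(init)[[2]], 0.1)
  lec0 <- -coef(init)[[1]] / n0
  df <- tibble::tibble(L = L, th = th)
  logL <- log(L)
  model <- function(par) {
    A <- if (amplitude == "free") par[["A"]] else 1
    A / (1 + exp(-par[["n"]] * (logL - par[["lec"]])))
  }
  start <- if (amplitude == "free") c(A = top, n = n0, lec = lec0)
           else c(n = n0, lec = lec0)
  lower <- if (amplitude == "free") c(1e-6, 1e-6, -Inf) else c(1e-6, -Inf)
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, fn = function(par) th - model(par),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  if (!fit$info %in% 1:4)
    abort(sprintf(
      "Hill fit did not converge (start n = %.3g, log EC50 = %.3g): %s",
      n0, lec0, fit$message))
  cf <- fit$par
  n_hat <- cf[["n"]]
  ec50 <- exp(cf[["lec"]])
  fitted <- model(cf)
  structure(
    list(n = n_hat, ec50 = ec50, K_d = ec50^n_hat,
         A = if (amplitude == "free") cf[["A"]] else 1,
         amplitude = amplitude,
         residuals = th - fitted, fitted = fitted,
         data = df, nobs = length(L)),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> n = %.4g, EC50 = %.4g, K_d = %.4g (units^n)%s\n",
              x$n, x$ec50, x$K_d,
              if (x$amplitude == "free") sprintf(", A = %.3g", x$A) else ""))
  invisible(x)
}

#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(term = c("n", "ec50", "K_d"),
                 estimate = c(x$n, x$ec50, x$K_d))
}

#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(n = x$n, ec50 = x$ec50, K_d = x$K_d, A = x$A,
                 rss = sum(x$residuals^2), nobs = x$nobs)
}

#' Severing rate
#'
#' Events per micrometre of filament per second.
#'
#' @param n_events Number of severing events observed.
#' @param total_filament_um Total filament length examined (um).
#' @param duration_s Observation time (s).
#' @return Rate in events um^-1 s^-1.
#' @export
#' @examples
#' severing_rate(6, 20, 100)  # 0.003
severing_rate <- function(n_events, total_filament_um, duration_s) {
  stopifnot(n_events >= 0)
  if (any(total_filament_um <= 0) || any(duration_s <= 0))
    abort("filament length and duration must be positive")
  n_events / (total_filament_um * duration_s)
}
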