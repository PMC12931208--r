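#' Eyring rate constant
#'
#' Transition-state rate `k = (kB * T / h) * exp(dS/R - dH/(R*T))` with
#' CODATA constants (see [physical_constants()]).
#'
#' @param dH Activation enthalpy (J mol^-1).
#' @param dS Activation entropy (J mol^-1 K^-1).
#' @param T_K Temperature(s) (K).
#' @return Rate constant(s) (s^-1).
#' @export
#' @examples
#' eyring_rate(0, 0, 298.15)        # kB*T/h = 6.212e12 s^-1
#' eyring_rate(25e3, 20, 298)
eyring_rate <- function(dH, dS, T_K) {
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop_param("`T_K` must be positive and finite")
  (.kB * T_K / .h) * exp(dS / .R - dH / (.R * T_K))
}

#' Eyring fit of temperature-dependent rates
#'
#' Ordinary least squares of `ln(k/T)` on `1/T` (the linearized Eyring plot):
#' the slope is `-dH/R` and the intercept `ln(kB/h) + dS/R`. The free energy
#' of activation at the reference temperature is `dG = dH - T_ref * dS`, with
#' its standard error propagated from the regression covariance.
#'
#' @param rates Data frame with columns `T_K` and `k_per_s` (at least 3
#'   distinct temperatures, all rates positive).
#' @param T_ref Reference temperature for `dG` (K, default 298).
#' @return An object of class `eyring_fit`: `dH`, `dS`, `dG` (J mol^-1 and
#'   J mol^-1 K^-1), standard errors `dH_se`, `dS_se`, `dG_se`, `T_ref`,
#'   `r_squared` and the underlying `lm` fit.
#' @export
#' @examples
#' tab <- simulate_temperature_series(25e3, 20, rel_noise = 0)
#' eyring_fit(tab)
eyring_fit <- function(rates, T_ref = 298) {
  if (!all(c("T_K", "k_per_s") %in% names(rates)))
    stop_param("`rates` must have columns `T_K` and `k_per_s`")
  T_K <- rates$T_K
  k <- rates$k_per_s
  if (any(!is.finite(T_K)) || any(T_K <= 0)) stop_param("temperatures must be positive")
  if (any(!is.finite(k)) || any(k <= 0)) stop_param("rates must be positive")
  if (length(unique(T_K)) < 3L)
    stop_param("need at least 3 distinct temperatures")
  check_positive(T_ref, "T_ref")
  dat <- data.frame(y = log(k / T_K), invT = 1 / T_K)
  fit <- lm(y ~ invT, data = dat)
  cf <- coef(fit)
  if (any(!is.finite(cf))) stop_param("degenerate temperature design")
  # noiseless round trips fit exactly; the perfect-fit warning is expected
  V <- suppressWarnings(vcov(fit))
  dH <- -cf[["invT"]] * .R
  dS <- (cf[["(Intercept)"]] - log(.kB / .h)) * .R
  dH_se <- sqrt(V["invT", "invT"]) * .R
  dS_se <- sqrt(V["(Intercept)", "(Intercept)"]) * .R
  # dG = dH - T_ref*dS = -R*(slope + T_ref*intercept - T_ref*log(kB/h))
  dG <- dH - T_ref * dS
  dG_var <- .R^2 * (V["invT", "invT"] + T_ref^2 * V["(Intercept)", "(Intercept)"] +
                      2 * T_ref * V["invT", "(Intercept)"])
  rss <- sum(residuals(fit)^2)
  tss <- sum((dat$y - mean(dat$y))^2)
  structure(list(dH = dH, dS = dS, dG = dG,
                 dH_se = dH_se, dS_se = dS_se, dG_se = sqrt(max(dG_var, 0)),
                 T_ref = T_ref,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 n = length(k), fit = fit),
            class = "eyring_fit")
}

#' Nonlinear Eyring refit (cross-check)
#'
#' Direct nonlinear least squares of `k = (kB*T/h) exp(dS/R - dH/(R*T))` on
#' the rate scale, initialized from the linearized [eyring_fit()]. Offered as
#' a cross-check: with homoscedastic relative errors the linearized fit is
#' standard practice; on the absolute rate scale the largest rates dominate.
#'
#' @inheritParams eyring_fit
#' @return A list with `dH`, `dS`, `dG`, their standard errors and `T_ref`.
#' @export
eyring_fit_nonlinear <- function(rates, T_ref = 298) {
  lin <- eyring_fit(rates, T_ref)
  dat <- data.frame(T_K = rates$T_K, k = rates$k_per_s)
  fit <- tryCatch(
    minpack.lm::nlsLM(k ~ (1.380649e-23 * T_K / 6.62607015e-34) *
                        exp(dS / 8.314462618 - dH / (8.314462618 * T_K)),
                      data = dat, start = list(dH = lin$dH, dS = lin$dS),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(dH = lin$dH, dS = lin$dS, dG = lin$dG,
                dH_se = lin$dH_se, dS_se = lin$dS_se, T_ref = T_ref,
                converged = FALSE))
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  list(dH = cf[["dH"]], dS = cf[["dS"]], dG = cf[["dH"]] - T_ref * cf[["dS"]],
       dH_se = se[["dH"]], dS_se = se[["dS"]], T_ref = T_ref,
       converged = TRUE)
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat("Eyring fit (ln(k/T) ~ 1/T, OLS)\n")
  cat(sprintf("  dH = %.3g +/- %.2g kJ/mol\n", x$dH / 1e3, x$dH_se / 1e3))
  cat(sprintf("  dS = %.3g +/- %.2g J/mol/K\n", x$dS, x$dS_se))
  cat(sprintf("  dG(%g K) = %.3g +/- %.2g kJ/mol\n",
              x$T_ref, x$dG / 1e3, x$dG_se / 1e3))
  cat(sprintf("  R^2 = %.4f over %d temperatures\n", x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.eyring_fit <- function(object, ...) {
  c(dH = object$dH, dS = object$dS, dG = object$dG)
}

#' @export
predict.eyring_fit <- function(object, newdata = NULL, ...) {
  T_K <- if (is.null(newdata)) stop_param("supply temperatures") else
    if (is.data.frame(newdata)) newdata$T_K else newdata
  eyring_rate(object$dH, object$dS, T_K)
}
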