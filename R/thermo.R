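check_rate_points <- function(points) {
  stopifnot(is.data.frame(points))
  if (!all(c("T_K", "k_per_s") %in% names(points))) {
    stop("'points' needs columns T_K and k_per_s", call. = FALSE)
  }
  if (any(points$T_K <= 0) || any(!is.finite(points$T_K))) {
    stop("temperatures must be finite and > 0 K", call. = FALSE)
  }
  if (any(points$k_per_s <= 0) || any(!is.finite(points$k_per_s))) {
    stop("rate constants must be finite and > 0", call. = FALSE)
  }
  if (length(unique(points$T_K)) < 2L) {
    stop("need at least 2 distinct temperatures", call. = FALSE)
  }
  points
}

#' Arrhenius analysis of a rate-temperature series
#'
#' Ordinary least squares of ln k on 1/T. The activation energy is
#' Ea = -slope * R (kcal/mol) and the intercept is ln A. Standard errors come
#' from the regression covariance; an optional `weights` vector (e.g. 1/se^2)
#' switches to weighted least squares.
#'
#' @param points data.frame with columns `T_K` and `k_per_s`, at least two
#'   distinct temperatures, all rates positive.
#' @param weights Optional regression weights.
#' @return An object of class `"arrhenius_fit"`: `Ea` (kcal/mol), `lnA`,
#'   `se_Ea`, `se_lnA`, `r2`, `df`.
#' @export
#' @examples
#' pts <- generate_temperature_series(eyring_params(20, 5), seq(278, 298, 5))
#' arrhenius_fit(pts)
arrhenius_fit <- function(points, weights = NULL) {
  points <- check_rate_points(points)
  x <- 1 / points$T_K
  y <- log(points$k_per_s)
  fit <- stats::lm(y ~ x, weights = weights)
  sm <- suppressWarnings(summary(fit))  # "perfect fit" warning on exact data
  cf <- sm$coefficients
  R <- opsin_constants$R_kcal
  structure(
    list(Ea = -unname(cf["x", "Estimate"]) * R,
         lnA = unname(cf["(Intercept)", "Estimate"]),
         se_Ea = unname(cf["x", "Std. Error"]) * R,
         se_lnA = unname(cf["(Intercept)", "Std. Error"]),
         r2 = sm$r.squared,
         df = fit$df.residual),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: Ea = %.4g +/- %.2g kcal/mol, lnA = %.4g (r2 = %.4f)\n",
              x$Ea, x$se_Ea, x$lnA, x$r2))
  invisible(x)
}

#' Eyring analysis of a rate-temperature series
#'
#' Ordinary least squares of ln(k/T) on 1/T. The transition-state enthalpy is
#' dH = -slope * R (kcal/mol) and the entropy is
#' dS = (intercept - ln(kB/h)) * R' (cal/(mol K)); the activation barrier
#' dG at `T_ref` is dH - T_ref dS / 1000 (kcal/mol). The transmission
#' coefficient is fixed at 1.
#'
#' @inheritParams arrhenius_fit
#' @param T_ref Reference temperature in K for the barrier (default 298).
#' @return An object of class `"eyring_fit"`: `dH` (kcal/mol), `dS`
#'   (cal/(mol K)), `dG298` (kcal/mol at `T_ref`), `se_dH`, `se_dS`, `r2`,
#'   `df`, `T_ref`.
#' @export
#' @examples
#' pts <- generate_temperature_series(eyring_params(21, 5), seq(278, 298, 5))
#' eyring_fit(pts)
eyring_fit <- function(points, weights = NULL, T_ref = 298) {
  points <- check_rate_points(points)
  stopifnot(T_ref > 0)
  x <- 1 / points$T_K
  y <- log(points$k_per_s / points$T_K)
  fit <- stats::lm(y ~ x, weights = weights)
  sm <- suppressWarnings(summary(fit))  # "perfect fit" warning on exact data
  cf <- sm$coefficients
  co <- opsin_constants
  dH <- -unname(cf["x", "Estimate"]) * co$R_kcal
  dS <- (unname(cf["(Intercept)", "Estimate"]) - log(co$kB / co$h)) * co$R_cal
  structure(
    list(dH = dH, dS = dS,
         dG298 = delta_g(dH, dS, T_ref),
         se_dH = unname(cf["x", "Std. Error"]) * co$R_kcal,
         se_dS = unname(cf["(Intercept)", "Std. Error"]) * co$R_cal,
         r2 = sm$r.squared,
         df = fit$df.residual,
         T_ref = T_ref),
    class = "eyring_fit"
  )
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat(sprintf("Eyring fit: dH = %.4g +/- %.2g kcal/mol, dS = %.4g +/- %.2g cal/(mol K)\n",
              x$dH, x$se_dH, x$dS, x$se_dS))
  cat(sprintf("  dG(%g K) = %.4g kcal/mol (r2 = %.4f)\n",
              x$T_ref, x$dG298, x$r2))
  invisible(x)
}

#' Activation free energy from enthalpy and entropy
#'
#' dG = dH - T dS, with dH in kcal/mol and dS in cal/(mol K) (hence the
#' factor of 1000).
#'
#' @param dH Activation enthalpy, kcal/mol.
#' @param dS Activation entropy, cal/(mol K).
#' @param T Temperature in K, > 0 (default 298).
#' @return Activation free energy in kcal/mol.
#' @export
#' @examples
#' delta_g(20, 10)   # 17.02
#' delta_g(20, -10)  # 22.98: a negative dS raises the barrier
delta_g <- function(dH, dS, T = 298) {
  if (any(T <= 0)) stop("'T' must be > 0 K", call. = FALSE)
  dH - T * dS / 1000
}

#' Celsius to Kelvin
#'
#' @param T_C Temperature(s) in degrees Celsius.
#' @return Temperature(s) in K.
#' @export
celsius_to_kelvin <- function(T_C) T_C + 273.15
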