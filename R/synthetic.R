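#' Simulate a retinal-release fluorescence trace
#'
#' Generates the tryptophan-fluorescence rise that accompanies retinal release
#' from a light-activated opsin: flat dark baseline before light onset, then a
#' monoexponential rise `baseline + A * (1 - exp(-k (t - t_hv)))`, with
#' additive i.i.d. Gaussian noise. Light onset is treated as instantaneous at
#' `t_hv` (the 2 s irradiation used experimentally is short relative to even
#' the fastest half-life modelled).
#'
#' @param preset A [release_preset()].
#' @param times Sampling times in s, strictly increasing, spanning beyond
#'   `preset$t_hv`.
#' @param seed Integer seed; identical seeds give bitwise-identical traces.
#'   `NULL` leaves the caller's RNG state untouched and unused when
#'   `noise_sd = 0`.
#' @return A [fluor_trace()] carrying the preset's metadata.
#' @export
#' @examples
#' p <- opsin_presets()$GCO_WT
#' tr <- generate_release_trace(p, seq(0, 120, 0.5), seed = 1)
generate_release_trace <- function(preset, times, seed = NULL) {
  stopifnot(inherits(preset, "release_preset"))
  times <- check_times(times)
  if (max(times) <= preset$t_hv) {
    stop("'times' must span beyond the light-onset time t_hv", call. = FALSE)
  }
  dt <- pmax(times - preset$t_hv, 0)
  f <- preset$baseline + preset$amplitude * (1 - exp(-preset$k * dt))
  f[times < preset$t_hv] <- preset$baseline
  if (preset$noise_sd > 0) {
    f <- f + with_seed(seed, stats::rnorm(length(times), 0, preset$noise_sd))
  }
  fluor_trace(times, f, t_hv = preset$t_hv, label = preset$label,
              temperature = preset$temperature, n_d2o = preset$n_d2o)
}

#' Eyring transition-state parameters
#'
#' @param dH Activation enthalpy, kcal/mol.
#' @param dS Activation entropy, cal/(mol K) (entropy units).
#' @return An object of class `"eyring_params"`.
#' @seealso [eyring_rate()], [generate_temperature_series()], [eyring_fit()]
#' @export
eyring_params <- function(dH, dS) {
  stopifnot(is.numeric(dH), is.numeric(dS))
  structure(list(dH = dH, dS = dS), class = "eyring_params")
}

#' Eyring rate at given temperatures
#'
#' k(T) = (kB T / h) exp(dS / R') exp(-dH / (R T)), with dH in kcal/mol
#' (R = 1.9872e-3 kcal/(mol K)) and dS in cal/(mol K)
#' (R' = 1.9872 cal/(mol K)); transmission coefficient fixed at 1.
#'
#' @param params An [eyring_params()] object.
#' @param temps Temperatures in K, all > 0.
#' @return Rate constants in 1/s.
#' @export
#' @examples
#' eyring_rate(eyring_params(0, 0), 298.15)  # kB T / h, about 6.21e12
eyring_rate <- function(params, temps) {
  stopifnot(inherits(params, "eyring_params"))
  if (any(!is.finite(temps)) || any(temps <= 0)) {
    stop("temperatures must be finite and > 0 K", call. = FALSE)
  }
  co <- opsin_constants
  (co$kB * temps / co$h) * exp(params$dS / co$R_cal) *
    exp(-params$dH / (co$R_kcal * temps))
}

#' Generate a rate-vs-temperature series
#'
#' Evaluates the Eyring equation at each temperature, optionally perturbing
#' each rate with multiplicative lognormal noise `k * exp(N(0, rel_noise))`
#' (rates are positive, so noise is applied on the log scale).
#'
#' @inheritParams eyring_rate
#' @param rel_noise Standard deviation of log-rate noise (0 = exact).
#' @param seed Integer seed for the noise.
#' @return A data.frame with columns `T_K` and `k_per_s` (one row per
#'   temperature), usable directly by [eyring_fit()] and [arrhenius_fit()].
#' @export
#' @examples
#' generate_temperature_series(eyring_params(20, 5), 278:282 + 0.15)
generate_temperature_series <- function(params, temps, rel_noise = 0,
                                        seed = NULL) {
  k <- eyring_rate(params, temps)
  if (rel_noise > 0) {
    k <- k * exp(with_seed(seed, stats::rnorm(length(k), 0, rel_noise)))
  }
  data.frame(T_K = as.numeric(temps), k_per_s = k)
}

#' Gross-Butler proton-inventory parameters
#'
#' @param k0 Rate constant in pure H2O, 1/s.
#' @param phis Per-site transition-state fractionation factors, all > 0. The
#'   number of sites is `length(phis)`.
#' @return An object of class `"gross_butler_params"`.
#' @export
gross_butler_params <- function(k0, phis) {
  stopifnot(k0 > 0, length(phis) >= 1L, all(phis > 0))
  structure(list(k0 = k0, phis = as.numeric(phis)),
            class = "gross_butler_params")
}

#' Gross-Butler relative rate
#'
#' k_n / k_0 = prod_j (1 - n + n phi_j): the rate in a solvent of D2O atom
#' fraction n relative to pure H2O, for transition-state fractionation
#' factors phi_j (ground-state factors fixed at 1). At n = 0 the ratio is
#' exactly 1 for any phi.
#'
#' @param phis Fractionation factors, all > 0.
#' @param n D2O atom fractions in \[0, 1\].
#' @return Relative rates k_n / k_0.
#' @export
#' @examples
#' gross_butler_rel_rate(0.5, 1)          # 0.5: single-site endpoint
#' gross_butler_rel_rate(c(0.5, 0.5), 0.5)  # 0.5625
gross_butler_rel_rate <- function(phis, n) {
  stopifnot(all(phis > 0))
  if (any(n < 0 | n > 1)) {
    stop("D2O atom fractions must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(1, length(n))
  for (phi in phis) out <- out * (1 - n + n * phi)
  out
}

#' Generate a proton-inventory series
#'
#' Evaluates the Gross-Butler relation at each D2O atom fraction and adds
#' i.i.d. Gaussian noise on the relative-rate scale.
#'
#' @param params A [gross_butler_params()] object.
#' @param n_values D2O atom fractions in \[0, 1\].
#' @param noise_sd Noise standard deviation on the relative rate.
#' @param seed Integer seed.
#' @return A data.frame with columns `n` (D2O fraction), `rel_rate`
#'   (k_n / k_0) and `k_per_s` (absolute rate).
#' @export
#' @examples
#' generate_proton_inventory_series(gross_butler_params(0.03, 0.65),
#'                                  seq(0, 1, length.out = 7))
generate_proton_inventory_series <- function(params, n_values, noise_sd = 0,
                                             seed = NULL) {
  stopifnot(inherits(params, "gross_butler_params"))
  rel <- gross_butler_rel_rate(params$phis, n_values)
  if (noise_sd > 0) {
    rel <- rel + with_seed(seed, stats::rnorm(length(rel), 0, noise_sd))
  }
  data.frame(n = as.numeric(n_values), rel_rate = rel,
             k_per_s = params$k0 * rel)
}

#' Transducin-activation assay parameters
#'
#' Parameters of the minimal pool-activation model: an active receptor
#' population decaying with first-order rate `k_decay` activates free Gt by
#' pseudo-second-order encounters (`k_act`, per nM per s). Fluorescence is a
#' linear combination of activated Gt and released retinal.
#'
#' @param R0 Initial active receptor concentration, nM.
#' @param Gtot Total Gt concentration, nM.
#' @param k_decay Receptor active-state decay rate, 1/s.
#' @param k_act Activation rate constant, 1/(nM s).
#' @param fl_per_gt Fluorescence yield per nM activated Gt, a.u./nM.
#' @param fl_per_retinal Fluorescence yield per nM released retinal, a.u./nM.
#' @param noise_sd Gaussian noise sd, a.u.
#' @return An object of class `"gt_assay_params"`.
#' @export
#' @examples
#' gt_assay_params(R0 = 15, Gtot = 300, k_decay = log(2) / 18, k_act = 2e-4)
gt_assay_params <- function(R0, Gtot, k_decay, k_act, fl_per_gt = 1,
                            fl_per_retinal = 1, noise_sd = 0) {
  vals <- c(R0 = R0, Gtot = Gtot, k_decay = k_decay, k_act = k_act,
            fl_per_gt = fl_per_gt, fl_per_retinal = fl_per_retinal,
            noise_sd = noise_sd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all Gt assay parameters must be finite and nonnegative",
         call. = FALSE)
  }
  structure(as.list(vals), class = "gt_assay_params")
}

#' Simulate a Gt-activation assay trace
#'
#' Light onset at t = 0. Without Gt (`with_gt = FALSE`, the experimental
#' control) fluorescence follows retinal release alone,
#' `fl_per_retinal * R0 * (1 - exp(-k_decay t))`. With Gt it additionally
#' carries `fl_per_gt * G*(t)` where G*(t) is the closed-form activated-Gt
#' time course of [simulate_gt()].
#'
#' @param params A [gt_assay_params()] object.
#' @param times Sampling times in s, strictly increasing, starting at or
#'   after light onset (t = 0).
#' @param seed Integer seed for the additive Gaussian noise.
#' @param with_gt Logical: include the Gt-activation component?
#' @return A [fluor_trace()] with `t_hv = 0` (values are already relative to
#'   the dark baseline).
#' @export
#' @examples
#' p <- gt_assay_params(15, 300, log(2) / 18, 2e-4)
#' tr <- generate_gt_assay_trace(p, seq(0, 600, 2), with_gt = TRUE)
generate_gt_assay_trace <- function(params, times, seed = NULL,
                                    with_gt = TRUE) {
  stopifnot(inherits(params, "gt_assay_params"))
  times <- check_times(times)
  if (any(times < 0)) {
    stop("Gt assay times are measured from light onset; all must be >= 0",
         call. = FALSE)
  }
  f <- params$fl_per_retinal * params$R0 * (1 - exp(-params$k_decay * times))
  if (with_gt) {
    f <- f + params$fl_per_gt * gt_pool_activated(params, times)
  }
  if (params$noise_sd > 0) {
    f <- f + with_seed(seed, stats::rnorm(length(times), 0, params$noise_sd))
  }
  fluor_trace(times, f, t_hv = 0,
              label = if (with_gt) "gt_assay" else "gt_control")
}
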