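#' Define a retinal-release preset
#'
#' A preset bundles the parameters of a monoexponential retinal-release
#' (meta II decay) measurement: the first-order rate constant (or,
#' equivalently, the half-life), the fluorescence amplitude and dark
#' baseline, the light-onset time, the noise level, and the assay
#' conditions. Exactly one of `k` and `t_half` must be supplied; the other
#' is derived through k = ln(2) / t_half.
#'
#' @param label Sample label.
#' @param k First-order decay rate constant, 1/s.
#' @param t_half Half-life, s.
#' @param amplitude Fluorescence rise amplitude, a.u. (> 0).
#' @param baseline Dark-state fluorescence level, a.u.
#' @param t_hv Light-onset time, s (>= 0).
#' @param noise_sd Gaussian noise standard deviation, a.u. (>= 0).
#' @param temperature Assay temperature, K.
#' @param n_d2o D2O atom fraction of the solvent in \[0, 1\].
#' @param note Free-text annotation.
#' @return An object of class `"release_preset"`.
#' @export
#' @examples
#' release_preset("GCO_WT", t_half = 18, temperature = 283.15)
release_preset <- function(label, k = NULL, t_half = NULL, amplitude = 1,
                           baseline = 0, t_hv = 10, noise_sd = 0,
                           temperature = NA_real_, n_d2o = 0, note = NULL) {
  if (is.null(k) == is.null(t_half)) {
    stop("supply exactly one of 'k' and 't_half'", call. = FALSE)
  }
  if (is.null(k)) {
    stopifnot(t_half > 0)
    k <- log(2) / t_half
  } else {
    stopifnot(k > 0)
    t_half <- log(2) / k
  }
  stopifnot(amplitude > 0, t_hv >= 0, noise_sd >= 0,
            n_d2o >= 0, n_d2o <= 1)
  structure(
    list(label = label, k = k, t_half = t_half, amplitude = amplitude,
         baseline = baseline, t_hv = t_hv, noise_sd = noise_sd,
         temperature = temperature, n_d2o = n_d2o, note = note),
    class = "release_preset"
  )
}

#' @export
print.release_preset <- function(x, ...) {
  cat(sprintf("Release preset '%s': t1/2 = %g s (k = %.4g 1/s), A = %g a.u.\n",
              x$label, x$t_half, x$k, x$amplitude))
  cat(sprintf("  baseline %g, hv at %g s, noise sd %g, T = %s K, n(D2O) = %g\n",
              x$baseline, x$t_hv, x$noise_sd,
              ifelse(is.na(x$temperature), "?", format(x$temperature)),
              x$n_d2o))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Shipped retinal-release presets
#'
#' Presets for wild-type human rhodopsin (Rho_WT), wild-type human green cone
#' opsin (GCO_WT) and the stabilising mutant GCO_E102Q, built from the mean
#' half-lives measured by tryptophan-fluorescence retinal-release assays at
#' 9-10 degrees C: 2188 s, 18 s and 139 s respectively, plus the H2O/D2O
#' pairs used for solvent-isotope work (GCO_WT 23.3/35.6 s, GCO_E102Q
#' 131.6/268.3 s at 9 degrees C). The source figure caption states 10 degrees
#' C while the accompanying text states 9 degrees C for the first three; the
#' discrepancy is recorded in each preset's `note` and left unresolved.
#'
#' @return A named list of [release_preset()] objects.
#' @export
#' @examples
#' names(opsin_presets())
#' opsin_presets()$GCO_WT
opsin_presets <- function() {
  note10 <- "temperature reported as 10 C in the figure, 9 C in the text"
  T9  <- 273.15 + 9
  T10 <- 273.15 + 10
  list(
    Rho_WT = release_preset("Rho_WT", t_half = 2188, temperature = T10,
                            note = note10),
    GCO_WT = release_preset("GCO_WT", t_half = 18, temperature = T10,
                            note = note10),
    GCO_E102Q = release_preset("GCO_E102Q", t_half = 139, temperature = T10,
                               note = note10),
    GCO_WT_H2O = release_preset("GCO_WT_H2O", t_half = 23.3,
                                temperature = T9, n_d2o = 0),
    GCO_WT_D2O = release_preset("GCO_WT_D2O", t_half = 35.6,
                                temperature = T9, n_d2o = 1),
    GCO_E102Q_H2O = release_preset("GCO_E102Q_H2O", t_half = 131.6,
                                   temperature = T9, n_d2o = 0),
    GCO_E102Q_D2O = release_preset("GCO_E102Q_D2O", t_half = 268.3,
                                   temperature = T9, n_d2o = 1)
  )
}
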