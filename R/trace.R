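#' Construct a fluorescence trace
#'
#' The raw observable of every kinetic stage: a time course of intrinsic
#' tryptophan fluorescence (330 nm) with the light-onset time and assay
#' metadata attached. Retinal release from an activated opsin and GDP/GTPgammaS
#' exchange on transducin both report as a rise in this signal.
#'
#' @param times Sampling times in seconds, strictly increasing.
#' @param values Fluorescence in arbitrary units, same length as `times`.
#' @param t_hv Light-onset time in seconds (metadata, never fitted).
#' @param label Sample label, e.g. `"GCO_WT"`.
#' @param temperature Assay temperature in K (optional metadata).
#' @param n_d2o D2O atom fraction of the solvent, in \[0, 1\].
#' @param baseline Dark baseline already subtracted from `values`, if any.
#' @return An object of class `"fluor_trace"`: a list with elements `times`,
#'   `values`, `t_hv` and `meta`.
#' @export
#' @examples
#' tr <- fluor_trace(0:10, c(rep(0, 3), 1 - exp(-0.2 * (3:10 - 2))), t_hv = 2)
#' print(tr)
fluor_trace <- function(times, values, t_hv = 0, label = NA_character_,
                        temperature = NA_real_, n_d2o = 0, baseline = NA_real_) {
  times <- check_times(times)
  if (length(values) != length(times)) {
    stop("'times' and 'values' must have equal length", call. = FALSE)
  }
  if (!is.numeric(t_hv) || length(t_hv) != 1L || t_hv < 0) {
    stop("'t_hv' must be a single nonnegative number", call. = FALSE)
  }
  if (!is.na(n_d2o) && (n_d2o < 0 || n_d2o > 1)) {
    stop("'n_d2o' must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(times = times, values = as.numeric(values), t_hv = t_hv,
         meta = list(label = label, temperature = temperature,
                     n_d2o = n_d2o, baseline = baseline)),
    class = "fluor_trace"
  )
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace '%s': %d samples, t = [%g, %g] s, hv at %g s\n",
              x$meta$label, length(x$times), min(x$times), max(x$times), x$t_hv))
  if (!is.na(x$meta$temperature)) {
    cat(sprintf("  temperature %.2f K, D2O fraction %.2f\n",
                x$meta$temperature, x$meta$n_d2o))
  }
  invisible(x)
}

#' @export
as.data.frame.fluor_trace <- function(x, ...) {
  data.frame(time_s = x$times, fluorescence_au = x$values)
}
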