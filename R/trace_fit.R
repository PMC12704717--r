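#' Convert between rate constant and half-life
#'
#' First-order kinetics identity k = ln(2) / t_half (and its inverse, which
#' has the same form).
#'
#' @param t_half Half-life in s, > 0.
#' @param k Rate constant in 1/s, > 0.
#' @return The corresponding rate constant (1/s) or half-life (s).
#' @export
#' @examples
#' rate_from_half_life(18)      # 0.03851 1/s
#' half_life_from_rate(3.168e-4)
rate_from_half_life <- function(t_half) {
  if (any(!is.finite(t_half)) || any(t_half <= 0)) {
    stop("'t_half' must be finite and > 0", call. = FALSE)
  }
  log(2) / t_half
}

#' @rdname rate_from_half_life
#' @export
half_life_from_rate <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("'k' must be finite and > 0", call. = FALSE)
  }
  log(2) / k
}

#' Subtract the dark baseline from a trace
#'
#' Averages the fluorescence recorded before light onset (t < t_hv) to obtain
#' the dark-state level and subtracts it, yielding the Delta-F signal that all
#' downstream fitting consumes. The subtracted level is recorded in the trace
#' metadata.
#'
#' @param trace A [fluor_trace()].
#' @return A baseline-subtracted [fluor_trace()] whose pre-onset mean is zero.
#' @export
#' @examples
#' tr <- generate_release_trace(opsin_presets()$GCO_WT, seq(0, 120, 0.5))
#' dtr <- subtract_dark_baseline(tr)
#' mean(dtr$values[dtr$times < dtr$t_hv])  # 0
subtract_dark_baseline <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  pre <- trace$times < trace$t_hv
  if (!any(pre)) {
    stop("no samples before t_hv: supply an explicit dark baseline instead",
         call. = FALSE)
  }
  dark <- mean(trace$values[pre])
  out <- trace
  out$values <- trace$values - dark
  out$meta$baseline <- dark
  out
}

#' Fit a monoexponential fluorescence rise
#'
#' Fits Delta-F(t) = A (1 - exp(-k (t - t_hv))) to the post-onset samples of a
#' baseline-subtracted trace by damped (Levenberg-Marquardt) least squares.
#' Starting values are analytic: A from the maximum Delta-F and k from a
#' log-linear regression of log(1 - Delta-F/A) on t - t_hv. The light-onset
#' time is metadata and is never fitted. Non-convergence or a nonpositive
#' fitted rate yields a flagged result (`converged = FALSE`), not an error.
#'
#' @param trace A baseline-subtracted [fluor_trace()] with at least 4 samples
#'   at t >= t_hv.
#' @return An object of class `"decay_fit"` with elements `k`, `t_half`
#'   (= ln 2 / k), `amplitude`, `baseline` (the level removed by
#'   [subtract_dark_baseline()], if recorded), `rmse`, `se_k`, `df` and
#'   `converged`.
#' @export
#' @examples
#' tr <- generate_release_trace(opsin_presets()$GCO_WT, seq(0, 120, 0.5))
#' fit_monoexponential(subtract_dark_baseline(tr))
fit_monoexponential <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  post <- trace$times >= trace$t_hv
  if (sum(post) < 4L) {
    stop("need at least 4 samples at t >= t_hv to fit", call. = FALSE)
  }
  tt <- trace$times[post] - trace$t_hv
  y <- trace$values[post]
  base <- trace$meta$baseline %||% NA_real_

  failed <- function() {
    structure(list(k = NA_real_, t_half = NA_real_, amplitude = NA_real_,
                   baseline = base, rmse = NA_real_, se_k = NA_real_,
                   df = length(tt) - 2L, converged = FALSE,
                   label = trace$meta$label),
              class = "decay_fit")
  }

  a0 <- max(y)
  if (!is.finite(a0) || a0 <= 0) return(failed())
  # log-linear start: y/a ~ 1 - exp(-k t) with a slightly inflated amplitude
  # so the log argument stays positive in the presence of noise
  ag <- 1.05 * a0
  z <- 1 - y / ag
  ok <- z > 1e-8 & tt > 0
  k0 <- if (sum(ok) >= 2L) {
    sl <- sum(tt[ok] * log(z[ok])) / sum(tt[ok]^2)
    if (is.finite(sl) && sl < 0) -sl else 1 / max(tt)
  } else {
    1 / max(tt)
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * (1 - exp(-k * tt)),
      start = list(A = a0, k = k0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed())

  cf <- stats::coef(fit)
  sm <- summary(fit)
  k <- unname(cf["k"])
  res <- stats::residuals(fit)
  out <- structure(
    list(k = k,
         t_half = if (k > 0) log(2) / k else NA_real_,
         amplitude = unname(cf["A"]),
         baseline = base,
         rmse = sqrt(mean(res^2)),
         se_k = unname(sm$coefficients["k", "Std. Error"]),
         df = length(tt) - 2L,
         converged = fit$convInfo$isConv && k > 0,
         label = trace$meta$label),
    class = "decay_fit"
  )
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Monoexponential fit: NOT converged (flagged)\n")
  }
  cat(sprintf("Monoexponential rise fit%s:\n",
              if (is.null(x$label) || is.na(x$label)) "" else
                paste0(" [", x$label, "]")))
  cat(sprintf("  k = %.6g 1/s (se %.3g), t1/2 = %.6g s\n",
              x$k, x$se_k, x$t_half))
  cat(sprintf("  amplitude = %.6g a.u., rmse = %.3g a.u.\n",
              x$amplitude, x$rmse))
  invisible(x)
}

#' Initial rate from the early post-onset window
#'
#' Ordinary least-squares slope of fluorescence against time over the window
#' (t_hv, t_hv + window], the apparent-initial-rate estimator used for
#' Gt-activation assays (default window 30 s after light onset).
#'
#' @param trace A [fluor_trace()] (baseline-subtracted for meaningful units).
#' @param window Window length in s after light onset, > 0.
#' @return A list of class `"initial_rate"`: `slope` (a.u./s), `window`,
#'   `r2`, `n_points`.
#' @export
#' @examples
#' p <- gt_assay_params(15, 300, log(2) / 18, 2e-4)
#' initial_rate(generate_gt_assay_trace(p, seq(0, 600, 2)), window = 30)
initial_rate <- function(trace, window = 30) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    stop("'window' must be a single positive number of seconds", call. = FALSE)
  }
  sel <- trace$times > trace$t_hv & trace$times <= trace$t_hv + window
  if (sum(sel) < 2L) {
    stop("need at least 2 samples in (t_hv, t_hv + window]", call. = FALSE)
  }
  fit <- stats::lm(y ~ t, data = data.frame(t = trace$times[sel],
                                            y = trace$values[sel]))
  sm <- suppressWarnings(summary(fit))  # "perfect fit" warning on exact data
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 window = window,
                 r2 = sm$r.squared,
                 n_points = sum(sel)),
            class = "initial_rate")
}

#' @export
print.initial_rate <- function(x, ...) {
  cat(sprintf("Initial rate: %.6g a.u./s over %g s window (n = %d, r2 = %.4f)\n",
              x$slope, x$window, x$n_points, x$r2))
  invisible(x)
}

#' Fraction of properly folded receptor from the purity ratio
#'
#' A purified visual pigment with every apoprotein carrying its chromophore
#' has a theoretical minimum protein-to-chromophore absorbance ratio
#' (A280/Amax, 2.5 for green cone opsin); the folded fraction of a
#' preparation is that minimum divided by the observed ratio.
#'
#' @param observed_ratio Observed A280/Amax, >= `theoretical_min`.
#' @param theoretical_min Theoretical minimal ratio, > 0 (default 2.5).
#' @return Folded fraction in (0, 1]. The exact quotient is returned without
#'   rounding.
#' @export
#' @examples
#' folded_fraction(3.3)  # 0.7576
folded_fraction <- function(observed_ratio, theoretical_min = 2.5) {
  stopifnot(is.numeric(observed_ratio), is.numeric(theoretical_min),
            theoretical_min > 0)
  if (any(observed_ratio < theoretical_min)) {
    stop("observed ratio below the theoretical minimum implies ",
         "super-stoichiometric chromophore", call. = FALSE)
  }
  theoretical_min / observed_ratio
}
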