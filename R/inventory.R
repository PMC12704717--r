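#' Solvent kinetic isotope effect
#'
#' KIE = k(H2O) / k(D2O). For first-order kinetics this equals
#' t_half(D2O) / t_half(H2O), so both parameterisations are accepted and agree
#' identically.
#'
#' @param h2o Rate constant (1/s) or half-life (s) measured in H2O, > 0.
#' @param d2o Matching value measured in D2O, > 0.
#' @param mode `"rates"` or `"half_lives"`, saying what `h2o`/`d2o` are.
#' @return The dimensionless solvent KIE.
#' @export
#' @examples
#' solvent_kie(131.6, 268.3, mode = "half_lives")  # 2.039 -> ~2.04
#' solvent_kie(23.3, 35.6, mode = "half_lives")    # 1.528
solvent_kie <- function(h2o, d2o, mode = c("rates", "half_lives")) {
  mode <- match.arg(mode)
  if (any(c(h2o, d2o) <= 0) || any(!is.finite(c(h2o, d2o)))) {
    stop("rates/half-lives must be finite and > 0", call. = FALSE)
  }
  switch(mode, rates = h2o / d2o, half_lives = d2o / h2o)
}

check_inventory_points <- function(points, min_n = 3L) {
  stopifnot(is.data.frame(points))
  if (!"n" %in% names(points)) {
    stop("'points' needs a column 'n' (D2O atom fraction)", call. = FALSE)
  }
  if (any(points$n < 0 | points$n > 1)) {
    stop("D2O atom fractions must lie in [0, 1]", call. = FALSE)
  }
  if (length(unique(points$n)) < 2L) {
    stop("all D2O fractions identical: inventory fit undetermined",
         call. = FALSE)
  }
  if (nrow(points) < min_n) {
    stop(sprintf("need at least %d inventory points", min_n), call. = FALSE)
  }
  if (!("rel_rate" %in% names(points)) && !("k_per_s" %in% names(points))) {
    stop("'points' needs a 'rel_rate' or a 'k_per_s' column", call. = FALSE)
  }
  points
}

# Linear-algebra core: both Gross-Butler site-count models are linear after a
# change of variables.
#   m = 1: rel(n) = (1-n) + phi n                     -> basis {(1-n), n}
#   m = 2: rel(n) = (1-n)^2 + s n(1-n) + p n^2,       -> basis {(1-n)^2,
#          s = phi1 + phi2, p = phi1 phi2                 n(1-n), n^2}
# With normalised rates (rel_rate given) the (1-n)-basis coefficient is fixed
# by rel(0) = 1; with raw rates k0 multiplies every basis function and is
# estimated jointly, which implements normalisation against the *fitted*
# rate at n = 0 rather than a single raw reference point.
gb_linear_fit <- function(n, y, m, normalized) {
  if (m == 1L) {
    X <- cbind(one_minus_n = 1 - n, n = n)
  } else {
    X <- cbind(one_minus_n2 = (1 - n)^2, cross = n * (1 - n), n2 = n^2)
  }
  if (normalized) {
    # first coefficient fixed at 1: move it to the offset
    yy <- y - X[, 1L]
    X <- X[, -1L, drop = FALSE]
    beta <- stats::lm.fit(X, yy)$coefficients
    coefs <- c(1, beta)
    k0 <- 1
  } else {
    beta <- stats::lm.fit(X, y)$coefficients
    k0 <- beta[[1L]]
    if (!is.finite(k0) || k0 <= 0) {
      stop("fitted rate at n = 0 is nonpositive; data are not a valid ",
           "proton inventory", call. = FALSE)
    }
    coefs <- beta / k0
  }
  pred_rel <- if (m == 1L) {
    (1 - n) + coefs[[2L]] * n
  } else {
    (1 - n)^2 + coefs[[2L]] * n * (1 - n) + coefs[[3L]] * n^2
  }
  rss <- sum((y - k0 * pred_rel)^2)
  list(coefs = coefs, k0 = k0, rss = rss,
       n_par = m + (!normalized))
}

gb_phis_from_coefs <- function(coefs, m, n, y, k0) {
  if (m == 1L) {
    phi <- coefs[[2L]]
    return(list(phis = max(phi, .Machine$double.eps), constrained = FALSE))
  }
  s <- coefs[[2L]]
  p <- coefs[[3L]]
  disc <- s^2 - 4 * p
  if (disc >= 0) {
    r <- sort((s + c(-1, 1) * sqrt(disc)) / 2)
    if (all(r > 0)) return(list(phis = r, constrained = FALSE))
  }
  # unconstrained quadratic has no valid factorisation: refit with equal
  # fractionation factors, a one-parameter bounded problem
  f <- function(phi) sum((y - k0 * (1 - n + n * phi)^2)^2)
  opt <- stats::optimize(f, c(1e-4, 20))
  list(phis = rep(opt$minimum, 2L), constrained = TRUE)
}

#' Fit a Gross-Butler proton-inventory model
#'
#' Least-squares fit of the relative rate
#' k_n / k_0 = prod_j (1 - n + n phi_j) over j = 1..m transition-state proton
#' sites, for m = 1 (exactly linear in the D2O fraction n, slope phi - 1) or
#' m = 2 (quadratic). Higher site counts are statistically unidentifiable with
#' the few D2O fractions of a typical inventory and are not supported. If the
#' points carry raw rates (`k_per_s`) instead of `rel_rate`, the rate in pure
#' H2O is fitted jointly and the rates are normalised against that fitted
#' value. The overall solvent KIE implied by the fit is 1 / prod(phi_j).
#'
#' @param points data.frame with column `n` plus `rel_rate` or `k_per_s`;
#'   at least 3 points with at least 2 distinct `n`.
#' @param m Number of proton-transfer sites, 1 or 2.
#' @return An object of class `"inventory_fit"`: `model` (`"single_site"` or
#'   `"two_site"`), `phis`, `kie`, `rss`, `k0`, `n_par`, `df`, and
#'   `constrained` (TRUE when a two-site fit was forced to equal phis because
#'   the unconstrained quadratic had no valid factorisation).
#' @export
#' @examples
#' pts <- data.frame(n = c(0, 0.5, 1), rel_rate = c(1, 0.75, 0.5))
#' gross_butler_fit(pts, m = 1)  # phi = 0.5, KIE = 2
gross_butler_fit <- function(points, m = 1L) {
  points <- check_inventory_points(points)
  if (!m %in% c(1L, 2L)) {
    stop("only m = 1 or m = 2 proton sites are supported", call. = FALSE)
  }
  m <- as.integer(m)
  normalized <- "rel_rate" %in% names(points)
  y <- if (normalized) points$rel_rate else points$k_per_s
  if (any(y <= 0)) stop("rates must be > 0", call. = FALSE)
  n <- points$n
  lf <- gb_linear_fit(n, y, m, normalized)
  ph <- gb_phis_from_coefs(lf$coefs, m, n, y, lf$k0)
  rss <- if (ph$constrained) {
    sum((y - lf$k0 * (1 - n + n * ph$phis[[1L]])^2)^2)
  } else {
    lf$rss
  }
  structure(
    list(model = if (m == 1L) "single_site" else "two_site",
         m = m,
         phis = unname(ph$phis),
         kie = 1 / prod(ph$phis),
         rss = rss,
         k0 = lf$k0,
         n_par = lf$n_par,
         df = nrow(points) - lf$n_par,
         constrained = ph$constrained),
    class = "inventory_fit"
  )
}

#' @export
print.inventory_fit <- function(x, ...) {
  cat(sprintf("Gross-Butler fit (%s): phi = %s, KIE = %.4g, RSS = %.3g\n",
              x$model, paste(signif(x$phis, 4), collapse = ", "),
              x$kie, x$rss))
  invisible(x)
}

#' Predicted relative rates from an inventory fit
#'
#' @param fit An `"inventory_fit"`.
#' @param n D2O atom fractions.
#' @return Predicted k_n / k_0 (exactly 1 at n = 0).
#' @export
predict_inventory <- function(fit, n) {
  stopifnot(inherits(fit, "inventory_fit"))
  gross_butler_rel_rate(fit$phis, n)
}

#' Select single-site vs two-site proton transfer
#'
#' Fits the one-site (linear) and two-site (curved) Gross-Butler models and
#' compares them by the extra-sum-of-squares F-test. The two-site model is
#' selected only when it improves the fit significantly at alpha = 0.05;
#' otherwise the simpler single-site model wins (ties included). A linear
#' inventory indicates a single transferred proton in the rate-limiting
#' Schiff-base hydrolysis step; curvature indicates a multisite transfer.
#'
#' @param points data.frame as for [gross_butler_fit()], with at least 4
#'   distinct D2O fractions.
#' @param alpha Significance level for preferring the two-site model.
#' @return An object of class `"inventory_selection"`: `selected`
#'   (`"single_site"` or `"two_site"`), `fit` (the selected
#'   [gross_butler_fit()] result), `fit_single`, `fit_two`, `rss_linear`,
#'   `rss_curved`, `f_stat`, `p_value`, `phis`, `kie`.
#' @export
#' @examples
#' pts <- generate_proton_inventory_series(gross_butler_params(1, 0.65),
#'                                         seq(0, 1, length.out = 7))
#' select_inventory_model(pts)$selected
select_inventory_model <- function(points, alpha = 0.05) {
  points <- check_inventory_points(points, min_n = 4L)
  if (length(unique(points$n)) < 4L) {
    stop("need at least 4 distinct D2O fractions for model comparison",
         call. = FALSE)
  }
  f1 <- gross_butler_fit(points, m = 1L)
  f2 <- gross_butler_fit(points, m = 2L)
  df2 <- nrow(points) - f2$n_par
  scale <- mean(points[[if ("rel_rate" %in% names(points)) "rel_rate"
                        else "k_per_s"]])^2
  if (f2$rss <= 1e-25 * scale || f1$rss <= 1e-25 * scale) {
    # both (or the simpler) essentially perfect: simpler model wins
    f_stat <- NA_real_
    p_value <- 1
  } else {
    f_stat <- (f1$rss - f2$rss) / 1 / (f2$rss / df2)
    p_value <- stats::pf(f_stat, 1, df2, lower.tail = FALSE)
  }
  two_wins <- is.finite(p_value) && p_value < alpha && f2$rss < f1$rss
  sel <- if (two_wins) f2 else f1
  structure(
    list(selected = sel$model,
         fit = sel,
         fit_single = f1,
         fit_two = f2,
         rss_linear = f1$rss,
         rss_curved = f2$rss,
         f_stat = f_stat,
         p_value = p_value,
         phis = sel$phis,
         kie = sel$kie,
         alpha = alpha),
    class = "inventory_selection"
  )
}

#' @export
print.inventory_selection <- function(x, ...) {
  cat(sprintf("Proton-inventory model selection: %s\n", x$selected))
  cat(sprintf("  RSS linear = %.3g, RSS curved = %.3g, F = %.3g, p = %.3g\n",
              x$rss_linear, x$rss_curved, x$f_stat, x$p_value))
  cat(sprintf("  phi = %s, KIE = %.4g\n",
              paste(signif(x$phis, 4), collapse = ", "), x$kie))
  invisible(x)
}
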