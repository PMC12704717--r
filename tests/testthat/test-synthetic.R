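test_that("release presets enforce the rate/half-life identity and bounds", {
  p <- release_preset("x", t_half = 23.3)
  expect_equal(p$k * p$t_half, log(2), tolerance = 1e-12)
  p2 <- release_preset("x", k = 0.05)
  expect_equal(p2$t_half, log(2) / 0.05, tolerance = 1e-12)
  expect_error(release_preset("x", k = 0.1, t_half = 10), "exactly one")
  expect_error(release_preset("x"), "exactly one")
  expect_error(release_preset("x", t_half = 10, noise_sd = -1))
  expect_error(release_preset("x", t_half = 10, n_d2o = 1.2))
  ps <- opsin_presets()
  expect_equal(ps$Rho_WT$t_half, 2188)
  expect_equal(ps$GCO_WT$t_half, 18)
  expect_equal(ps$GCO_E102Q$t_half, 139)
})

test_that("release traces follow the monoexponential rise exactly when noiseless", {
  p <- release_preset("half", t_half = 18, amplitude = 1, baseline = 0,
                      t_hv = 0)
  tr <- generate_release_trace(p, c(0.5, 1, 18, 36))
  expect_equal(tr$values[tr$times == 18], 0.5, tolerance = 1e-12)
  expect_equal(tr$values[tr$times == 36], 0.75, tolerance = 1e-12)

  p2 <- release_preset("base", t_half = 50, amplitude = 2, baseline = 3,
                       t_hv = 20)
  t2 <- seq(0, 300, 1)
  tr2 <- generate_release_trace(p2, t2)
  expect_true(all(tr2$values[t2 < 20] == 3))
  expected <- 3 + 2 * (1 - exp(-p2$k * (t2[t2 >= 20] - 20)))
  expect_equal(tr2$values[t2 >= 20], expected, tolerance = 1e-10)
})

test_that("release trace generation is seed-deterministic and validates input", {
  p <- release_preset("n", t_half = 23.3, noise_sd = 0.01)
  t <- seq(0, 120, 0.5)
  a <- generate_release_trace(p, t, seed = 1)
  b <- generate_release_trace(p, t, seed = 1)
  expect_identical(a$values, b$values)
  c <- generate_release_trace(p, t, seed = 2)
  expect_false(identical(a$values, c$values))
  expect_error(generate_release_trace(p, c(1, 1, 2)), "increasing")
  expect_error(generate_release_trace(p, numeric(0)), "non-empty")
  expect_error(generate_release_trace(p, c(0, 1, 2)), "span beyond")
})

test_that("generators leave the caller's global RNG state untouched", {
  set.seed(99)
  expected <- rnorm(3)
  set.seed(99)
  p <- release_preset("n", t_half = 18, noise_sd = 0.01)
  invisible(generate_release_trace(p, seq(0, 60, 1), seed = 7))
  invisible(generate_proton_inventory_series(gross_butler_params(1, 0.5),
                                             c(0, 0.5, 1), 0.01, seed = 3))
  expect_identical(rnorm(3), expected)
})

test_that("temperature series follow the Eyring equation and invert exactly", {
  # prefactor-only limit
  k <- eyring_rate(eyring_params(0, 0), 298.15)
  expect_equal(k, opsin_constants$kB * 298.15 / opsin_constants$h,
               tolerance = 1e-12)
  expect_equal(k, 6.21e12, tolerance = 1e-3)
  # direct evaluation with a barrier
  k20 <- eyring_rate(eyring_params(20, 0), 298.15)
  expect_equal(k20,
               (opsin_constants$kB * 298.15 / opsin_constants$h) *
                 exp(-20 / (opsin_constants$R_kcal * 298.15)),
               tolerance = 1e-12)
  expect_error(eyring_rate(eyring_params(20, 0), -5), "> 0 K")

  # two points determine the two parameters: round trip through eyring_fit
  for (p in list(eyring_params(21, 5), eyring_params(15, -12))) {
    pts <- generate_temperature_series(p, c(280, 300))
    fit <- eyring_fit(pts)
    expect_equal(fit$dH, p$dH, tolerance = 1e-9)
    expect_equal(fit$dS, p$dS, tolerance = 1e-9)
  }
})

test_that("proton-inventory series follow the Gross-Butler relation", {
  expect_equal(gross_butler_rel_rate(1.0, c(0, 0.3, 1)), c(1, 1, 1))
  expect_equal(gross_butler_rel_rate(0.5, 1), 0.5)
  expect_equal(gross_butler_rel_rate(c(0.5, 0.5), 0.5), 0.5625,
               tolerance = 1e-12)
  expect_error(gross_butler_rel_rate(0.5, 1.5), "\\[0, 1\\]")
  ser <- generate_proton_inventory_series(gross_butler_params(0.03, 0.65),
                                          seq(0, 1, 0.25))
  expect_equal(ser$rel_rate, (1 - ser$n + ser$n * 0.65), tolerance = 1e-12)
  expect_equal(ser$k_per_s, 0.03 * ser$rel_rate, tolerance = 1e-12)
  a <- generate_proton_inventory_series(gross_butler_params(1, 0.5),
                                        seq(0, 1, 0.2), 0.01, seed = 4)
  b <- generate_proton_inventory_series(gross_butler_params(1, 0.5),
                                        seq(0, 1, 0.2), 0.01, seed = 4)
  expect_identical(a, b)
})

test_that("Gt assay traces have the correct control and activation structure", {
  p <- gt_assay_params(R0 = 15, Gtot = 300, k_decay = 0.02, k_act = 3e-4,
                       fl_per_gt = 1, fl_per_retinal = 0.5)
  t <- seq(0, 2000, 5)
  ctrl <- generate_gt_assay_trace(p, t, with_gt = FALSE)
  # control plateaus at full retinal release
  expect_equal(ctrl$values[length(t)], 0.5 * 15, tolerance = 1e-8)
  # no activation -> with_gt identical to control
  p0 <- gt_assay_params(15, 300, 0.02, 0, fl_per_gt = 1,
                        fl_per_retinal = 0.5)
  expect_equal(generate_gt_assay_trace(p0, t, with_gt = TRUE)$values,
               generate_gt_assay_trace(p0, t, with_gt = FALSE)$values)
  # k_act R0 / k_decay = ln 2 halves the pool at t -> Inf
  ph <- gt_assay_params(15, 300, k_decay = 3e-4 * 15 / log(2), k_act = 3e-4,
                        fl_per_gt = 1, fl_per_retinal = 0)
  tr <- generate_gt_assay_trace(ph, c(1e5, 2e5), with_gt = TRUE)
  expect_equal(tr$values[2], 300 / 2, tolerance = 1e-6)
  expect_error(gt_assay_params(-1, 300, 0.1, 1e-4), "nonnegative")
})

test_that("toy shell structures are valid and reject bad specs", {
  s <- generate_toy_structure(10, 1.7, 500)
  expect_s3_class(s, "opsin_structure")
  expect_equal(nrow(s), 500)
  r <- sqrt(s$x^2 + s$y^2 + s$z^2)
  expect_equal(r, rep(10, 500), tolerance = 1e-9)
  # quasi-uniform coverage: nearest-neighbour gaps closed for the probe
  d <- as.matrix(dist(cbind(s$x, s$y, s$z)))
  diag(d) <- Inf
  expect_lt(max(apply(d, 1, min)), 2 * (1.7 + 1.4))
  expect_error(generate_toy_structure(10, 1.7, 0), "positive")
  expect_error(generate_toy_structure(10, 12, 100), "atom_radius")
  lig <- opsin_structure(0, 0, 0, vdw = 1.7)
  s2 <- generate_toy_structure(10, 1.7, 500, ligand = lig)
  expect_equal(sum(s2$resid == "LIG"), 1)
})
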