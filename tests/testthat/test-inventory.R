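test_that("solvent KIE handles both parameterisations identically", {
  expect_equal(solvent_kie(131.6, 268.3, mode = "half_lives"), 268.3 / 131.6)
  expect_equal(round(solvent_kie(131.6, 268.3, mode = "half_lives"), 2), 2.04)
  expect_equal(solvent_kie(23.3, 35.6, mode = "half_lives"), 1.528,
               tolerance = 1e-3)
  expect_equal(solvent_kie(1, 1), 1.0)
  # rates and half-lives agree exactly for first-order kinetics
  expect_equal(solvent_kie(log(2) / 23.3, log(2) / 35.6, mode = "rates"),
               solvent_kie(23.3, 35.6, mode = "half_lives"),
               tolerance = 1e-12)
  expect_error(solvent_kie(0, 1), "> 0")
})

test_that("Gross-Butler fits invert exact single- and two-site data", {
  pts <- data.frame(n = c(0, 0.5, 1), rel_rate = c(1, 0.75, 0.5))
  fit <- gross_butler_fit(pts, m = 1)
  expect_equal(fit$phis, 0.5, tolerance = 1e-12)
  expect_equal(fit$kie, 2, tolerance = 1e-12)
  expect_equal(predict_inventory(fit, 0), 1)

  two <- generate_proton_inventory_series(gross_butler_params(1, c(0.5, 0.5)),
                                          seq(0, 1, 0.25))
  fit2 <- gross_butler_fit(two, m = 2)
  expect_equal(fit2$phis, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(fit2$kie, 4, tolerance = 1e-8)

  asym <- generate_proton_inventory_series(gross_butler_params(2, c(0.4, 0.9)),
                                           seq(0, 1, 1 / 6))
  fit3 <- gross_butler_fit(asym, m = 2)
  expect_equal(fit3$phis, c(0.4, 0.9), tolerance = 1e-9)

  flat <- data.frame(n = c(0, 0.3, 0.7, 1), rel_rate = rep(1, 4))
  fit4 <- gross_butler_fit(flat, m = 1)
  expect_equal(fit4$phis, 1, tolerance = 1e-12)
  expect_equal(fit4$kie, 1, tolerance = 1e-12)

  expect_error(gross_butler_fit(pts, m = 3), "m = 1 or m = 2")
  expect_error(gross_butler_fit(data.frame(n = c(0.5, 0.5, 0.5),
                                           rel_rate = c(1, 1, 1))),
               "identical")
})

test_that("raw-rate inventories are normalised against the fitted k0", {
  gb <- gross_butler_params(0.0297, 0.62)
  ser <- generate_proton_inventory_series(gb, seq(0, 1, 0.2))
  ser$rel_rate <- NULL
  fit <- gross_butler_fit(ser, m = 1)
  expect_equal(fit$k0, 0.0297, tolerance = 1e-9)
  expect_equal(fit$phis, 0.62, tolerance = 1e-9)
})

test_that("single-site fits satisfy KIE = 1/phi and monotone predictions", {
  for (phi in c(0.3, 0.65, 0.9)) {
    ser <- generate_proton_inventory_series(gross_butler_params(1, phi),
                                            seq(0, 1, 0.25), 0.005, seed = 2)
    fit <- gross_butler_fit(ser, m = 1)
    expect_equal(fit$kie * fit$phis, 1, tolerance = 1e-12)
    pred <- predict_inventory(fit, seq(0, 1, 0.1))
    expect_true(all(diff(pred) < 0))
    expect_equal(pred[1], 1)
  }
})

test_that("model selection distinguishes single- from two-site transfer", {
  n_vals <- seq(0, 1, length.out = 7)
  n_seeds <- 50
  single_wins <- two_wins <- 0
  for (s in seq_len(n_seeds)) {
    one <- generate_proton_inventory_series(gross_butler_params(1, 0.65),
                                            n_vals, 0.01, seed = s)
    if (select_inventory_model(one)$selected == "single_site") {
      single_wins <- single_wins + 1
    }
    two <- generate_proton_inventory_series(
      gross_butler_params(1, c(0.5, 0.5)), n_vals, 0.01, seed = s)
    if (select_inventory_model(two)$selected == "two_site") {
      two_wins <- two_wins + 1
    }
  }
  expect_gte(single_wins, 45)
  expect_gte(two_wins, 45)
})

test_that("perfectly linear data select single-site with zero linear RSS", {
  pts <- generate_proton_inventory_series(gross_butler_params(1, 0.7),
                                          seq(0, 1, length.out = 5))
  sel <- select_inventory_model(pts)
  expect_equal(sel$selected, "single_site")
  expect_lt(sel$rss_linear, 1e-20)
  expect_error(select_inventory_model(pts[1:3, ]), "at least 4")
})

test_that("D2O trace series round-trip through trace fitting to the phi value", {
  phi <- 0.654
  k0 <- log(2) / 23.3
  n_vals <- seq(0, 1, length.out = 7)
  k_fit <- vapply(seq_along(n_vals), function(i) {
    kn <- k0 * (1 - n_vals[i] + n_vals[i] * phi)
    p <- release_preset(sprintf("n%0.2f", n_vals[i]), k = kn,
                        noise_sd = 0.02, t_hv = 10, n_d2o = n_vals[i])
    tr <- generate_release_trace(p, seq(0, 10 + 6 / kn, length.out = 300),
                                 seed = 100 + i)
    fit_monoexponential(subtract_dark_baseline(tr))$k
  }, numeric(1))
  fit <- gross_butler_fit(data.frame(n = n_vals, k_per_s = k_fit), m = 1)
  expect_lt(abs(fit$phis - phi) / phi, 0.05)
})
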