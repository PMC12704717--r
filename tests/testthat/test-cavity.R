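# Unit-scale cavity checks run on a small shell (radius 7 A, 500 atoms) so
# each detector call stays fast; the full-size shell is exercised in the
# acceptance suite.

test_that("grid specification validates its geometry", {
  g <- grid_spec()
  expect_equal(g$spacing, 0.6)
  expect_equal(g$probe_in, 1.4)
  expect_equal(g$probe_out, 4.0)
  expect_error(grid_spec(spacing = 2), "spacing")
  expect_error(grid_spec(probe_out = 1), "probe_out")
  expect_error(detect_cavities(generate_toy_structure(7, 1.5, 500),
                               grid_spec(spacing = 0.6, max_points = 100)),
               "coarser spacing")
})

test_that("shell cavity volume matches the flood-fill oracle", {
  shell <- generate_toy_structure(7, 1.5, 500)
  cs <- detect_cavities(shell, grid_spec())
  expect_equal(cs$cavity_count, 1)
  v <- cs$cavities[[1]]$volume
  oracle <- oracle_enclosed_volumes(cbind(shell$x, shell$y, shell$z),
                                    shell$vdw, probe = 1.4, spacing = 0.25)
  expect_equal(length(oracle), 1)
  expect_lt(abs(v - oracle[1]) / oracle[1], 0.10)
  # and the analytic enclosed sphere is the same thing
  expect_lt(abs(oracle[1] - 4 / 3 * pi * (7 - 1.5 - 1.4)^3) / oracle[1],
            0.05)
})

test_that("an isolated atom has no cavities", {
  atom <- opsin_structure(0, 0, 0, element = "C")
  expect_equal(detect_cavities(atom)$cavity_count, 0)
})

test_that("halving the grid spacing changes the volume by less than 5%", {
  shell <- generate_toy_structure(7, 1.5, 500)
  v1 <- detect_cavities(shell, grid_spec(spacing = 0.6))$cavities[[1]]$volume
  v2 <- detect_cavities(shell, grid_spec(spacing = 0.3))$cavities[[1]]$volume
  expect_lt(abs(v1 - v2) / v2, 0.05)
})

test_that("nested concentric shells yield two cavities, matching the oracle", {
  outer_shell <- generate_toy_structure(c(16, 8), 1.5, c(2000, 800))
  cs <- detect_cavities(outer_shell, grid_spec())
  oracle <- oracle_enclosed_volumes(
    cbind(outer_shell$x, outer_shell$y, outer_shell$z),
    outer_shell$vdw, probe = 1.4, spacing = 0.35)
  expect_equal(cs$cavity_count, length(oracle))
  expect_equal(cs$cavity_count, 2)
  for (i in 1:2) {
    expect_lt(abs(cs$cavities[[i]]$volume - oracle[i]) / oracle[i], 0.10)
  }
})

test_that("ligand vdW volume counts the union of spheres", {
  carbon <- opsin_structure(0, 0, 0, element = "C")
  v1 <- ligand_volume(carbon, spacing = 0.25)
  expect_lt(abs(v1 - 4 / 3 * pi * 1.7^3) / (4 / 3 * pi * 1.7^3), 0.02)
  # disjoint atoms add
  two <- opsin_structure(c(0, 10), 0, 0, element = "C")
  expect_lt(abs(ligand_volume(two, spacing = 0.25) - 2 * v1) / (2 * v1),
            0.02)
  # coincident atoms do not double-count
  co <- opsin_structure(c(0, 0), c(0, 0), c(0, 0), element = "C")
  expect_equal(ligand_volume(co, spacing = 0.25), v1, tolerance = 1e-9)
  # Richardson refinement: |V(h) - V(h/2)| shrinks under halving
  vols <- vapply(c(0.5, 0.25, 0.125),
                 function(h) ligand_volume(carbon, spacing = h), numeric(1))
  expect_lt(abs(vols[2] - vols[3]), abs(vols[1] - vols[2]))
})

test_that("water capacity floors volume times the standard number density", {
  expect_identical(water_capacity(1454.3), 48L)
  expect_identical(water_capacity(842.4), 28L)
  expect_identical(water_capacity(0), 0L)
  # monotone nondecreasing in volume
  v <- seq(0, 2000, 25)
  expect_true(all(diff(water_capacity(v)) >= 0))
  expect_error(water_capacity(-1), ">= 0")
  # first-principles density: 0.2% below the conventional 3.35e-2
  expect_equal(h2o_per_cubic_angstrom(), 3.35e-2, tolerance = 2e-3)
  expect_equal(h2o_per_cubic_angstrom(molar_mass = 18.015), 0.033428,
               tolerance = 1e-4)
})

test_that("cavity report selects the ligand's cavity and nets out its volume", {
  lig <- opsin_structure(c(0, 1.4), 0, 0, element = "C")
  shell <- generate_toy_structure(8, 1.5, 600, ligand = lig)
  rep <- cavity_report(shell, ligand = "LIG", grid = grid_spec())
  expect_equal(rep$v_net, rep$v_gross - rep$v_ligand, tolerance = 1e-9)
  expect_identical(rep$n_water, water_capacity(rep$v_net))
  # gross volume is the ligand-free shell cavity
  bare <- generate_toy_structure(8, 1.5, 600)
  v_bare <- detect_cavities(bare, grid_spec())$cavities[[1]]$volume
  expect_equal(rep$v_gross, v_bare, tolerance = 1e-9)
  # a ligand far outside every cavity is an error that lists cavities
  far <- opsin_structure(50, 50, 50, element = "C")
  shell_far <- rbind(bare, {
    x <- far
    x$resid <- "LIG"
    x
  })
  class(shell_far) <- c("opsin_structure", "data.frame")
  expect_error(cavity_report(shell_far, ligand = "LIG"), "none of the")
})

test_that("cavity volume is invariant under rigid motion within tolerance", {
  shell <- generate_toy_structure(7, 1.5, 500)
  v0 <- detect_cavities(shell, grid_spec())$cavities[[1]]$volume
  # a fixed arbitrary proper rotation + translation
  ang <- c(0.7, -0.4, 1.9)
  Rz <- matrix(c(cos(ang[1]), sin(ang[1]), 0,
                 -sin(ang[1]), cos(ang[1]), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[3]), sin(ang[3]),
                 0, -sin(ang[3]), cos(ang[3])), 3)
  xyz <- cbind(shell$x, shell$y, shell$z) %*% t(Rz %*% Rx)
  moved <- opsin_structure(xyz[, 1] + 3.17, xyz[, 2] - 8.2, xyz[, 3] + 0.33,
                           vdw = shell$vdw)
  v1 <- detect_cavities(moved, grid_spec())$cavities[[1]]$volume
  expect_lt(abs(v1 - v0) / v0, 0.05)
})
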