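test_that("area per lipid follows V / (tau * phi)", {
  expect_equal(area_per_lipid(782, 20, 1), 39.1)
  expect_equal(area_per_lipid(782, 20, 0.5), 2 * area_per_lipid(782, 20, 1))
  expect_error(area_per_lipid(782, 0, 0.5), "tau")
  expect_error(area_per_lipid(782, 20, 0), "phi")
  # strictly decreasing in both tau and phi
  expect_true(all(diff(area_per_lipid(782, seq(10, 20, 2), 0.9)) < 0))
  expect_true(all(diff(area_per_lipid(782, 15, seq(0.5, 1, 0.1))) < 0))
  # inversion: generate tau from a target area and recover it
  set.seed(8)
  for (i in 1:20) {
    A <- runif(1, 40, 70); phi <- runif(1, 0.6, 1)
    tau <- 782 / (A * phi)
    expect_equal(area_per_lipid(782, tau, phi), A, tolerance = 1e-9)
  }
})

test_that("phase assignment separates fluid from gel packing", {
  expect_equal(assign_phase(57.4), "liquid_crystalline")
  expect_equal(assign_phase(49.0), "liquid_crystalline")
  expect_equal(assign_phase(45.4), "gel")
  expect_equal(assign_phase(45.0), "gel")
  # tie goes to the fluid side, and the threshold is configurable
  expect_equal(assign_phase(47), "liquid_crystalline")
  expect_equal(assign_phase(46, threshold = 44), "liquid_crystalline")
  expect_error(assign_phase(-1), "positive")
})

test_that("helix length is linear in residue count", {
  expect_equal(helix_length(21), 3.15)
  expect_equal(helix_length(0), 0)
  expect_equal(helix_length(42), 2 * helix_length(21))
  expect_equal(helix_length(10, rise_per_residue = 2), 2)
  expect_error(helix_length(-1), "non-negative")
})

test_that("volume fraction decomposition handles the pure limits", {
  lip <- c(d2o = 6.8e-6, h2o = -0.37e-6)
  pep <- c(d2o = 3.9e-6, h2o = 2.9e-6)
  solv <- c(d2o = 6.36e-6, h2o = -0.56e-6)
  pure_lip <- peptide_volume_fraction(lip, lip, pep, solv)
  expect_equal(pure_lip$phi_peptide, 0, tolerance = 1e-12)
  expect_equal(pure_lip$phi_solvent, 0, tolerance = 1e-12)
  expect_equal(pure_lip$phi_lipid, 1, tolerance = 1e-12)
  pure_solv <- peptide_volume_fraction(solv, lip, pep, solv)
  expect_equal(pure_solv$phi_solvent, 1, tolerance = 1e-12)
  expect_error(peptide_volume_fraction(lip[1], lip[1], pep[1], solv[1]),
               "2 contrasts")
  # degenerate pair: solvent indistinguishable from lipid
  expect_error(peptide_volume_fraction(lip, lip, pep, lip + 1e-16),
               "degenerate")
})

test_that("decomposition flags clipping on out-of-range solutions", {
  lip <- c(6.8e-6, -0.37e-6)
  pep <- c(3.9e-6, 2.9e-6)
  solv <- c(6.36e-6, -0.56e-6)
  layer <- 1.4 * lip - 0.4 * solv   # unphysical composition
  dec <- peptide_volume_fraction(layer, lip, pep, solv)
  expect_true(dec$clipped)
  expect_gte(dec$phi_solvent, 0)
})

test_that("orientation scenarios invert their own generative models", {
  p <- maculatin1()
  mats <- default_materials()
  # three contrasts so the uneven scenario is genuinely over-determined
  f <- c(d2o = 1, smw = 0.6, h2o = 0)
  solv <- c(6.36e-6, 0.6 * 6.36e-6 + 0.4 * -0.56e-6, -0.56e-6)
  lip <- vapply(f, function(x) material_sld(mats$tails_h, x), 0)
  pn <- vapply(f, function(x) peptide_sld(p, x, "n_half"), 0)
  pc <- vapply(f, function(x) peptide_sld(p, x, "c_half"), 0)
  pw <- vapply(f, function(x) peptide_sld(p, x, "whole"), 0)

  # oriented N-in truth: shared fraction, N-half inner
  s_in <- 0.74 * lip + 0.18 * pn + 0.08 * solv
  s_out <- 0.74 * lip + 0.18 * pc + 0.08 * solv
  sc <- orientation_scenarios(s_in, s_out, p, lip, solv, f)
  expect_lt(sc$residuals["n_in"], 1e-12)
  expect_lt(sc$residuals["n_in"], sc$residuals["n_out"])
  expect_lt(sc$residuals["n_in"], sc$residuals["uneven"])
  expect_equal(sc$selected, "n_in")
  expect_equal(sc$n_in$phi_peptide, 0.18, tolerance = 1e-9)

  # uneven truth: whole peptide at unequal fractions
  s_in2 <- 0.75 * lip + 0.17 * pw + 0.08 * solv
  s_out2 <- 0.71 * lip + 0.21 * pw + 0.08 * solv
  sc2 <- orientation_scenarios(s_in2, s_out2, p, lip, solv, f)
  expect_lt(sc2$residuals["uneven"], 1e-12)
  expect_equal(sc2$selected, "uneven")
  expect_equal(sc2$uneven$inner$phi_peptide, 0.17, tolerance = 1e-9)
  expect_equal(sc2$uneven$outer$phi_peptide, 0.21, tolerance = 1e-9)
})

test_that("swapping leaflets swaps the oriented residuals exactly", {
  p <- maculatin1()
  f <- c(1, 0)
  lip <- c(6.8e-6, -0.37e-6)
  solv <- c(6.36e-6, -0.56e-6)
  s_in <- c(5.9e-6, 0.6e-6)
  s_out <- c(5.6e-6, 0.2e-6)
  a <- orientation_scenarios(s_in, s_out, p, lip, solv, f)
  b <- orientation_scenarios(s_out, s_in, p, lip, solv, f)
  expect_equal(a$n_in$residual, b$n_out$residual)
  expect_equal(a$n_out$residual, b$n_in$residual)
  expect_equal(a$uneven$inner$phi_peptide, b$uneven$outer$phi_peptide)
})

test_that("symmetric labelling makes orientations undecidable", {
  expect_error(
    orientation_scenarios(c(1e-6, 2e-6), c(1e-6, 2e-6), maculatin1("none"),
                          c(6.8e-6, -0.37e-6), c(6.36e-6, -0.56e-6),
                          c(1, 0)),
    "symmetric")
})

test_that("uncertainty wider than the half-SLD contrast flags indistinguishable", {
  p <- maculatin1()
  f <- c(1, 0)
  mats <- default_materials()
  lip <- vapply(f, function(x) material_sld(mats$tails_h, x), 0)
  solv <- c(6.36e-6, -0.56e-6)
  pn <- vapply(f, function(x) peptide_sld(p, x, "n_half"), 0)
  pc <- vapply(f, function(x) peptide_sld(p, x, "c_half"), 0)
  s_in <- 0.74 * lip + 0.18 * pn + 0.08 * solv
  s_out <- 0.74 * lip + 0.18 * pc + 0.08 * solv
  big <- rep(5e-7, 2)   # larger than the leaflet SLD contrast itself
  sc <- orientation_scenarios(s_in, s_out, p, lip, solv, f,
                              sld_inner_err = big, sld_outer_err = big)
  expect_true(sc$indistinguishable)
})
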