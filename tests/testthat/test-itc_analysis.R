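mk_series <- function(heats, vols = rep(1, length(heats)), cell_mM = 5,
                      cell_ul = 200, syr_mM = 20) {
  itc_series(vols, heats, syringe_mM = syr_mM, cell_mM = cell_mM,
             cell_volume_ul = cell_ul)
}

test_that("the molar-ratio axis is strictly increasing and dilution-aware", {
  s <- mk_series(rep(-1, 39))
  expect_true(all(diff(s$molar_ratio) > 0))
  # without dilution the final ratio would be 39*20/(5*200); the perfusion
  # correction leaves slightly more
  expect_gt(s$molar_ratio[39], 39 * 20 / (5 * 200))
})

test_that("the priming injection is dropped and recorded when present", {
  s <- itc_series(c(0.2, rep(1, 5)), c(-9, rep(-1, 5)), 20, 5, 200,
                  first_injection_discarded = FALSE)
  expect_length(s$heats_uJ, 5L)
  expect_equal(unname(s$discarded_first["volume_ul"]), 0.2)
})

test_that("blank subtraction removes the dilution component", {
  a <- mk_series(rep(-2.5, 10))
  b <- mk_series(rep(-0.5, 10))
  expect_equal(subtract_blank(a, b)$heats_uJ, rep(-2, 10))
  expect_equal(subtract_blank(a, a)$heats_uJ, rep(0, 10))
  bad <- mk_series(rep(-0.5, 10), vols = c(rep(1, 4), 2, rep(1, 5)))
  expect_error(subtract_blank(a, bad), "injection 5")
  short <- mk_series(rep(-0.5, 9))
  expect_error(subtract_blank(a, short), "counts differ")

  it <- sim_itc_pair(seed = 81)
  cleaned <- subtract_blank(it$raw$mg, it$raw$blank)
  expect_equal(cleaned$heats_uJ, it$mg$heats_uJ, tolerance = 1e-10)
})

test_that("total heat normalizes by cell moles with exact units", {
  # 3 x -1 uJ over 5 mM x 200 ul = 1 umol: -3 J/mol = -0.003 kJ/mol
  s <- mk_series(rep(-1, 3))
  expect_equal(total_heat(s), -0.003)
  z <- mk_series(rep(0, 4))
  expect_equal(total_heat(z), 0)
})

test_that("synthetic full titrations integrate to the designed total", {
  it <- sim_itc_pair(dH_mg = -2.9, n_injections = 78L, seed = 82)
  expect_equal(total_heat(it$mg), -2.9 * it$truth$coverage_final,
               tolerance = 1e-10)
  expect_lt(abs(total_heat(it$mg) - (-2.9)), 0.01)
})

test_that("refill stitching continues the cumulative accounting", {
  vols <- rep(1, 39)
  p1 <- mk_series(rep(-1, 39))
  # second part starts where the first left off
  p2 <- itc_series(vols, rep(-0.5, 39), 20, 5, 200,
                   analyte_dilution = p1$analyte_dilution_end,
                   titrant_nmol_start = p1$titrant_nmol_end)
  stitched <- stitch_refills(list(p1, p1))
  expect_length(stitched$heats_uJ, 78L)
  expect_true(all(diff(stitched$molar_ratio) > 0))
  # cumulative axis of the stitched series continues across the seam
  expect_equal(stitched$molar_ratio[40:78], p2$molar_ratio, tolerance = 1e-12)
  expect_identical(stitch_refills(list(p1)), p1)
  other <- itc_series(vols, rep(-1, 39), 20, 7, 200)
  expect_error(stitch_refills(list(p1, other)), "inconsistent")
})

test_that("total heat is additive under stitching", {
  p1 <- mk_series(rep(-1, 20))
  p2 <- mk_series(rep(-0.25, 20))
  expect_equal(total_heat(stitch_refills(list(p1, p2))),
               total_heat(p1) + total_heat(p2))
})

test_that("delta-delta-H identities hold", {
  full <- delta_delta_H(-10, -7, -3)
  expect_equal(full$ddH, -3)
  expect_equal(full$release_fraction, 1)
  none <- delta_delta_H(-8, -8, -3)
  expect_equal(none$ddH, 0)
  expect_equal(none$release_fraction, 0)
  expect_error(delta_delta_H(-10, -7, 0), "undefined")
})

test_that("delta-delta-H is antisymmetric in its binding arguments", {
  set.seed(83)
  for (i in 1:5) {
    a <- rnorm(1, -10); b <- rnorm(1, -7); m <- -2.9
    expect_equal(delta_delta_H(a, b, m)$ddH, -delta_delta_H(b, a, m)$ddH)
  }
})

test_that("synthetic full-release pairs satisfy the enthalpy identity", {
  it <- sim_itc_pair(release_fraction = 1, noise_uJ = 0, seed = 84)
  dH_mg <- total_heat(it$mg)
  dd <- delta_delta_H(total_heat(it$pep_minus), total_heat(it$pep_plus),
                      dH_mg)
  expect_lt(abs(dd$ddH - dH_mg) / abs(dH_mg), 0.02)
})

test_that("partial release fractions are recovered with propagated error", {
  fracs <- vapply(1:5, function(sd) {
    it <- sim_itc_pair(release_fraction = 0.5, noise_uJ = 2, seed = 850 + sd)
    delta_delta_H(total_heat(it$pep_minus), total_heat(it$pep_plus),
                  total_heat(it$mg))$release_fraction
  }, numeric(1))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.5), 3 * se + 0.02)
})
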