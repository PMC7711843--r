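test_that("reconstitution copy numbers reproduce the printed worked example", {
  vamp <- copy_number(140e-9, 50e-6, 80)
  syt <- copy_number(70e-9, 50e-6, 80)
  tsn <- copy_number(250e-9, 250e-6, 80)
  expect_equal(vamp$outward, 44, tolerance = 2 / 44)
  expect_equal(syt$outward, 22, tolerance = 2 / 22)
  expect_equal(tsn$outward, 15, tolerance = 2 / 15)
  expect_equal(vamp$lipids, pi * 80^2 / 0.65)
  expect_identical(copy_number(0, 50e-6, 80)$outward, 0)
})

test_that("copy numbers scale linearly in protein and quadratically in diameter", {
  base <- copy_number(100e-9, 50e-6, 80)$total
  expect_equal(copy_number(300e-9, 50e-6, 80)$total, 3 * base)
  expect_equal(copy_number(100e-9, 50e-6, 160)$total, 4 * base)
})

test_that("bridging span is the unfolded contour length plus offset", {
  expect_identical(bridging_span(0, 0), 0)
  expect_equal(bridging_span(38, 0), 38 * 0.365)
  expect_equal(bridging_span(38, 39), 77 * 0.365)
  expect_equal(bridging_span(10, 10, contour_per_residue = 0.5,
                             folded_offset = 2), 12)
  # default zippering parameters span the longest generated separations
  expect_gte(bridging_span(38, 39) + 1, 26)
})

test_that("steric exclusion is strict below the complex diameter", {
  big <- snare_complex("SNAREpin-CpxII-Syt1-Syt1")
  small <- snare_complex("SNAREpin-CpxII")
  expect_equal(big$diameter, 8)
  expect_equal(small$diameter, 3)
  expect_true(is_excluded(big, 7))
  expect_false(is_excluded(small, 5))
  expect_false(is_excluded(big, 8))      # boundary: not excluded
  expect_true(is_excluded(small, 2.999))
  expect_equal(is_excluded(big, c(0, 7.9, 8, 12)),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_error(snare_complex("custom"), "diameter")
})
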