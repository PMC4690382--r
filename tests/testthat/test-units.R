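test_that("physical dimensions convert to model units preserving proportions", {
  mu <- to_model_units(physical_dims(400, 8, spindle_length_um = 60))
  expect_equal(mu$cell_cross_section, 100)
  expect_equal(mu$furrow_width, 2)
  expect_equal(mu$spindle_length, 15)
  expect_equal(mu$um_per_unit, 4)

  ## identity when the quantity equals the cross-section
  expect_equal(to_model_units(physical_dims(400, 399.99))$furrow_width,
               99.9975)
  ## small egg: micrometres map one-to-one at the default scale
  expect_equal(to_model_units(physical_dims(100, 13))$furrow_width, 13)
})

test_that("conversion is scale invariant under joint rescaling", {
  set.seed(42)
  base <- to_model_units(physical_dims(400, 8, 60))
  for (k in runif(5, 0.1, 20)) {
    scaled <- to_model_units(physical_dims(400 * k, 8 * k, 60 * k))
    expect_equal(scaled$furrow_width, base$furrow_width)
    expect_equal(scaled$spindle_length, base$spindle_length)
  }
})

test_that("invalid dimensions are rejected", {
  expect_error(physical_dims(-400, 8), "positive")
  expect_error(physical_dims(400, 0), "positive")
  expect_error(physical_dims(100, 120), "smaller")
  expect_error(model_scale(0), "positive")
})
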