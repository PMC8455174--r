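test_that("final size solves Z = 1 - exp(-R0 Z) at the printed anchors", {
  expect_equal(round(final_size(4), 2), 0.98)
  expect_equal(final_size(0.5), 0)
  expect_equal(final_size(1), 0)
  # closed-form self-consistency at an arbitrary supercritical value
  z <- final_size(2.2)
  expect_equal(z, 1 - exp(-2.2 * z), tolerance = 1e-9)
  expect_error(final_size(-1), class = "popsir_invalid_input")
})

test_that("final size is monotone in R0, bounded below 1, and near 1 when R0 > 6", {
  grid <- seq(0, 50, by = 0.5)
  z <- final_size(grid)
  expect_true(all(diff(z) >= 0))
  expect_true(all(z < 1))
  expect_true(all(z >= 0))
  expect_true(all(z[grid > 6] > 0.99))
  # very large R0 must not break the bracket
  expect_true(all(final_size(c(1e3, 1e6)) < 1))
})

test_that("inversion is exact on the supercritical branch", {
  expect_equal(invert_final_size(0), 1)
  for (x in c(1.5, 3, 10)) {
    expect_equal(invert_final_size(final_size(x)), x, tolerance = 1e-7)
  }
  expect_equal(round(invert_final_size(0.98), 2), 3.99)
  expect_error(invert_final_size(1), class = "popsir_invalid_input")
  expect_error(invert_final_size(-0.1), class = "popsir_invalid_input")
})
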