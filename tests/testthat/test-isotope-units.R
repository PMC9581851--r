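test_that("delta to atom percent matches hand-computed references", {
  # 100 * 0.0036765 / 1.0036765
  expect_equal(delta_to_atom_percent(0), 0.36630331, tolerance = 1e-7)
  expect_equal(round(delta_to_atom_percent(0), 2), 0.37)
  # doubled ratio at +1000 per mil
  expect_equal(round(delta_to_atom_percent(1000), 4), 0.7299)
  expect_equal(natural_abundance_atpct(), delta_to_atom_percent(0))
  expect_error(delta_to_atom_percent(-1000), "exceed -1000")
})

test_that("delta/atom-percent conversions invert each other and are monotone", {
  expect_lt(abs(atom_percent_to_delta(0.3663)), 0.05)
  expect_lt(abs(atom_percent_to_delta(0.7299) - 1000), 0.1)
  deltas <- c(-900, -10, 0, 500, 1000, 1e5)
  back <- atom_percent_to_delta(delta_to_atom_percent(deltas))
  expect_equal(back, deltas, tolerance = 1e-9)
  withr::with_seed(11, {
    d <- sort(runif(200, -900, 1e5))
    at <- delta_to_atom_percent(d)
    expect_equal(atom_percent_to_delta(at), d, tolerance = 1e-9)
    expect_true(all(diff(at) > 0))
  })
  expect_error(atom_percent_to_delta(0), "strictly between")
  expect_error(atom_percent_to_delta(100), "strictly between")
})

test_that("atom percent excess is plain subtraction with exact inverse", {
  expect_equal(atom_percent_excess(9.24, 0.37), 8.87)
  expect_identical(atom_percent_excess(0.37, 0.37), 0)
  # negative APE is representable; validity is decided downstream
  expect_equal(atom_percent_excess(0.30, 0.37), -0.07)
  withr::with_seed(12, {
    a <- runif(100, 0, 100)
    b <- runif(100, 0, 100)
    expect_identical(atom_percent_excess(a, b) + b, a)
  })
  expect_error(atom_percent_excess(101, 0.37), "\\[0, 100\\]")
})
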