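test_that("percent of maximum enrichment rescales between background and ceiling", {
  expect_equal(percent_of_max(10, 10, 0.37), 100)
  expect_equal(percent_of_max(0.37, 10, 0.37), 0)
  expect_equal(round(percent_of_max(7.1, 10, 0.37), 1), 69.9)
  expect_error(percent_of_max(5, 0.3, 0.37), "headroom")
  expect_warning(percent_of_max(12, 10, 0.37), "outside")
})

test_that("percent of maximum is invariant under a common affine rescaling", {
  withr::with_seed(51, {
    at <- runif(50, 0.5, 9); mx <- runif(50, 9.5, 15); bg <- runif(50, 0, 0.4)
    base <- percent_of_max(at, mx, bg)
    a <- 0.6; b <- 2
    expect_equal(percent_of_max(a * at + b, a * mx + b, a * bg + b), base,
                 tolerance = 1e-10)
  })
})

test_that("screening flags background, ceiling violations and net production", {
  recs <- data.frame(
    sample_id = c("bg-like", "too-hot", "pulse"),
    conc_ppm = c(0.30, 0.35, 75),
    atpct_15N = c(0.41, 12, 6.2),
    max_at = c(10, 10, 10))
  out <- suppressWarnings(screen_n2o(recs))
  expect_identical(out$at_background, c(TRUE, FALSE, FALSE))
  expect_identical(out$exceeds_ceiling, c(FALSE, TRUE, FALSE))
  expect_identical(out$net_production, c(FALSE, FALSE, TRUE))
  expect_identical(out$sample_id, recs$sample_id)  # metadata carried through
  expect_error(screen_n2o(data.frame(conc_ppm = 1)), "columns")
})

test_that("physically simulated mixtures never trip the ceiling flag", {
  withr::with_seed(52, {
    sims <- simulate_n2o(pool_at = runif(300, 1, 15),
                         produced_ppm = runif(300, 0, 100),
                         transfer_discount = runif(300))
    out <- suppressWarnings(screen_n2o(sims))
    expect_false(any(out$exceeds_ceiling))
  })
})
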