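test_that("pool-mode tracer plans hit the expected initial enrichment", {
  plan <- plan_tracer(100, "pool", bg_at = 0.3663)
  expect_identical(plan$mode, "pool")
  expect_equal(plan$predicted_pool, 110)
  expect_equal(plan$tracer_n, 10)
  expect_identical(plan$carrier_n, 0)
  # (10 * 98 + 100 * 0.3663) / 110
  expect_equal(round(plan$predicted_at0, 2), 9.24)
  expect_lte(plan$predicted_at0, plan$label_enrichment)
  # too-small pools trigger the advisory to spike instead
  expect_warning(plan_tracer(5, "pool"), "spike")
})

test_that("spike-mode plans mix 10:90 label:carrier at the floor size", {
  plan <- plan_tracer(0, "spike", bg_at = 0.37)
  expect_equal(plan$predicted_pool, 15)
  expect_equal(plan$tracer_n, 1.5)
  expect_equal(plan$carrier_n, 13.5)
  # 0.1 * 98 + 0.9 * 0.37
  expect_equal(round(plan$predicted_at0, 2), 10.13)
})

test_that("tracer plans conserve 15N mass and seed the simulator consistently", {
  withr::with_seed(31, {
    for (i in 1:20) {
      native <- runif(1, 0, 500)
      mode <- sample(c("pool", "spike"), 1)
      plan <- suppressWarnings(
        plan_tracer(native, mode, target_fraction = runif(1, 0.05, 0.3),
                    bg_at = 0.3663))
      lhs <- plan$predicted_pool * plan$predicted_at0
      rhs <- plan$native_pool * 0.3663 + plan$tracer_n * plan$label_enrichment +
        plan$carrier_n * 0.3663
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  })
  # the planned state is exactly the simulator's t -> 0 state
  plan <- plan_tracer(100, "pool", bg_at = 0.3663)
  tr <- pool_trajectory(0, gp = 12, gc = 30, c0 = plan$predicted_pool,
                        at0 = plan$predicted_at0, bg_at = 0.3663)
  expect_equal(tr$at, plan$predicted_at0)
  expect_equal(tr$conc, plan$predicted_pool)
})

test_that("extract concentrations convert to a dry-matter basis", {
  expect_equal(extract_to_dm(1, fresh_mass_g = 4, dm_fraction = 0.5,
                             extractant_volume_mL = 30), 15)
  base <- extract_to_dm(2.5, 5, 0.4, 30, dilution_factor = 1)
  expect_equal(extract_to_dm(2.5, 5, 0.4, 30, dilution_factor = 5), 5 * base)
  expect_identical(extract_to_dm(0, 4, 0.5, 30), 0)
  expect_error(extract_to_dm(1, 0, 0.5, 30))
})
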