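test_that("blank correction follows the mass-balance formula", {
  # zero blank is the identity
  expect_identical(blank_correct(5.0, 100, 0.37, 0), 5.0)
  # (5*100 - 0.37*10) / 90
  expect_equal(blank_correct(5.0, 100, 0.37, 10), 5.514444, tolerance = 1e-6)
  # a blank at the sample's own abundance changes nothing
  expect_equal(blank_correct(0.37, 100, 0.37, 10), 0.37)
  expect_error(blank_correct(5, 10, 0.37, 10), "n_meas > n_blk")
  # dominating blank pushes the corrected value negative -> warn, don't clamp
  expect_warning(out <- blank_correct(0.1, 100, 0.37, 90), "outside")
  expect_lt(out, 0)
})

test_that("gross rate equations reproduce hand-worked examples", {
  dt <- 5 / 6
  expect_equal(gross_production(10, 8, 0, dt, 10, 8), 2.4, tolerance = 1e-12)
  expect_equal(gross_consumption(10, 8, 0, dt, 10, 8), 4.8, tolerance = 1e-12)
  # equal concentrations: analytic 0/0 limit
  expect_equal(gross_production(10, 10, 0, 1, 10, 5), 10 * log(2))
  expect_equal(gross_consumption(10, 10, 0, 1, 10, 5), 10 * log(2))
  # no dilution: GP = 0 and GC carries the concentration change alone
  expect_equal(gross_production(10, 8, 0, 1, 7, 7), 0)
  expect_equal(gross_consumption(10, 8, 0, 1, 7, 7), 2.0)
  expect_error(gross_production(10, -1, 0, 1, 5, 4), "positive")
  expect_error(gross_production(10, 9, 0, 1, 0, 4), "positive")
  expect_error(gross_production(10, 9, 1, 1, 5, 4), "later")
})

test_that("GP - GC equals the net concentration change for any valid input", {
  withr::with_seed(21, {
    n <- 2000
    c1 <- runif(n, 5, 1000)
    c2 <- c1 * runif(n, 0.3, 3)
    dt <- runif(n, 0.1, 2)
    ape1 <- runif(n, 0.5, 15)
    ape2 <- ape1 * runif(n, 0.05, 0.99)
    gp <- gross_production(c1, c2, 0, dt, ape1, ape2)
    gc <- gross_consumption(c1, c2, 0, dt, ape1, ape2)
    net <- (c2 - c1) / dt
    expect_equal(gp - gc, net, tolerance = 1e-10)
    # common rescaling of both enrichments cancels
    expect_equal(gross_production(c1, c2, 0, dt, 3.7 * ape1, 3.7 * ape2), gp)
    expect_equal(gross_consumption(c1, c2, 0, dt, 3.7 * ape1, 3.7 * ape2), gc)
  })
})

test_that("the general formula converges to the analytic limit near c1 = c2", {
  lim <- gross_production(10, 10, 0, 1, 10, 5)
  for (eps in c(1e-8, -1e-8)) {
    gen <- gross_production(10, 10 * (1 + eps), 0, 1, 10, 5, conc_tol = 1e-12)
    expect_equal(gen, lim, tolerance = 1e-6)
    gen_c <- gross_consumption(10, 10 * (1 + eps), 0, 1, 10, 5, conc_tol = 1e-12)
    expect_equal(gen_c, lim, tolerance = 1e-6)
  }
})

test_that("rates applied to the closed-form trajectory recover the truth", {
  cases <- expand.grid(gp = c(0.5, 12, 50, 300), gc = c(0.5, 30, 50, 300))
  for (i in seq_len(nrow(cases))) {
    gp <- cases$gp[i]; gc <- cases$gc[i]
    tr <- pool_trajectory(c(4, 24) / 24, gp, gc, c0 = 600, at0 = 9.24)
    gp_hat <- gross_production(tr$conc[1], tr$conc[2], 4 / 24, 1,
                               tr$ape[1], tr$ape[2])
    gc_hat <- gross_consumption(tr$conc[1], tr$conc[2], 4 / 24, 1,
                                tr$ape[1], tr$ape[2])
    expect_equal(gp_hat, gp, tolerance = 1e-10)
    expect_equal(gc_hat, gc, tolerance = 1e-10)
  }
})

test_that("compute_rates applies corrections, pairs records and excludes violations", {
  bg <- bg_ref(0.37)
  # enrichment rising over time violates the dilution assumption
  r <- compute_rates(rec(100, 9.24, 4), rec(95, 9.47, 24), bg, no_blank)
  expect_false(r$valid)
  expect_identical(r$exclusion_reason, "enrichment increased")
  expect_true(is.na(r$gp))
  # unlabeled-level enrichment gives no usable excess
  r <- compute_rates(rec(100, 0.37, 4), rec(95, 0.37, 24), bg, no_blank)
  expect_false(r$valid)
  expect_identical(r$exclusion_reason, "non-positive APE")
  # a decline below the noise tolerance is not accepted either
  r <- compute_rates(rec(100, 9.24, 4), rec(100, 9.24 - 1e-8, 24), bg, no_blank)
  expect_false(r$valid)
  expect_identical(r$exclusion_reason, "enrichment did not decline")
  # mismatched lineage is an error, not an exclusion
  expect_error(
    compute_rates(c(rec(100, 9, 4), reactor_id = "A"),
                  c(rec(95, 8, 24), reactor_id = "B"), bg, no_blank),
    "lineage")
  expect_error(
    compute_rates(rec(100, 9, 4), rec(95, 8, 24),
                  list(at_meas = 5, tracer_mode = "pool"), no_blank),
    "unlabeled")
})

test_that("compute_rates recovers simulated truth through the blank correction", {
  sim <- simulate_pool(sim_config(gp_true = 12, gc_true = 30,
                                  c0 = 110, at0 = 9.24, blank_n_ug = 5))
  inc <- sim$incubations
  lab <- inc[inc$tracer_mode != "none", ]
  bg <- inc[inc$tracer_mode == "none", ]
  r <- compute_rates(
    rec(lab$conc_mgN_per_kgDM[1], lab$atpct_15N[1], lab$time_h[1],
        lab$n_total_ug[1]),
    rec(lab$conc_mgN_per_kgDM[2], lab$atpct_15N[2], lab$time_h[2],
        lab$n_total_ug[2]),
    bg_ref(bg$atpct_15N), as.list(sim$blanks))
  expect_true(r$valid)
  expect_equal(r$gp, 12, tolerance = 1e-8)
  expect_equal(r$gc, 30, tolerance = 1e-8)
  expect_equal(r$net, -18, tolerance = 1e-8)
})

test_that("mean residence time is pool over flux", {
  expect_equal(mean_residence_time(1000, 50), 20)
  expect_equal(mean_residence_time(7, 7), 1)
  expect_equal(mean_residence_time(604, 302), 2)
  expect_error(mean_residence_time(100, 0), "positive")
})
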