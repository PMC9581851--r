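test_that("closed-form trajectory agrees with independent ODE integration", {
  cases <- data.frame(gp = c(12, 50, 50, 0.5), gc = c(30, 50, 5, 300))
  for (i in seq_len(nrow(cases))) {
    gp <- cases$gp[i]; gc <- cases$gc[i]
    tr <- pool_trajectory(c(4, 24) / 24, gp, gc, c0 = 600, at0 = 9.24,
                          bg_at = 0)
    ode <- ode_ape(c(4, 24) / 24, gp, gc, c0 = 600, ape0 = 9.24)
    expect_equal(tr$conc, ode$conc, tolerance = 1e-8)
    expect_equal(tr$ape, ode$ape, tolerance = 1e-8)
  }
})

test_that("simulated label mass balances the consumption integral", {
  for (p in list(c(12, 30), c(50, 50), c(80, 10))) {
    gp <- p[1]; gc <- p[2]
    a <- function(t) pool_trajectory(t, gp, gc, 600, 9.24, bg_at = 0)$ape
    lab <- function(t) pool_trajectory(t, gp, gc, 600, 9.24, bg_at = 0)$conc * a(t)
    removed <- stats::integrate(a, 0, 1, rel.tol = 1e-13)$value * gc
    expect_equal(lab(0) - lab(1), removed, tolerance = 1e-10)
  }
})

test_that("degenerate and one-sided regimes behave as physics dictates", {
  # no turnover: every record equals the initial state
  sim <- simulate_pool(sim_config(0, 0, c0 = 110, at0 = 9.24, blank_n_ug = 0))
  lab <- sim$incubations[sim$incubations$tracer_mode != "none", ]
  expect_equal(lab$conc_mgN_per_kgDM, c(110, 110))
  expect_equal(lab$atpct_15N, c(9.24, 9.24))
  # pure dilution: enrichment falls while the pool grows
  tr <- pool_trajectory(seq(0.05, 1, by = 0.05), gp = 40, gc = 0,
                        c0 = 110, at0 = 9.24)
  expect_true(all(diff(tr$ape) < 0))
  expect_true(all(diff(tr$conc) > 0))
  # exhausting the pool within the window is a scenario error
  expect_error(simulate_pool(sim_config(0, 200, c0 = 100, at0 = 9.24)),
               "exhausted")
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(12, 30, c0 = 110, at0 = 9.24,
                    noise_conc_cv = 0.05, noise_at_sd = 0.1, seed = 99)
  expect_identical(simulate_pool(cfg)$incubations,
                   simulate_pool(cfg)$incubations)
  s1 <- simulate_study(study_scenario(), seed = 42)
  s2 <- simulate_study(study_scenario(), seed = 42)
  expect_identical(s1$incubations, s2$incubations)
  expect_identical(s1$n2o, s2$n2o)
  expect_identical(s1$truth, s2$truth)
})

test_that("noiseless study simulations are recovered exactly by the pipeline", {
  sc <- study_scenario(noise_conc_cv = 0, noise_at_sd = 0,
                       reactor_cv = 0, pool_cv = 0, n_reactors = 2)
  study <- simulate_study(sc, seed = 5)
  rates <- ipd_rates(study$incubations, study$blanks)
  expect_true(all(rates$valid))
  joined <- merge(rates, study$truth,
                  by = c("reactor_id", "day", "assay"))
  expect_equal(joined$gp, joined$gp_true, tolerance = 1e-8)
  expect_equal(joined$gc, joined$gc_true, tolerance = 1e-8)
  # and the group SE of recovered rates collapses to zero
  summ <- summarize_rates(rates)
  expect_true(all(abs(summ$se) < 1e-10))
})

test_that("forced-invalid pairs are injected at the requested fraction", {
  sc <- study_scenario(noise_conc_cv = 0, noise_at_sd = 0,
                       exclusion_fraction = 1)
  study <- simulate_study(sc, seed = 7)
  rates <- ipd_rates(study$incubations, study$blanks)
  expect_true(all(!rates$valid))
  expect_true(all(rates$exclusion_reason == "enrichment increased"))
  expect_true(all(study$truth$forced_invalid))
})

test_that("headspace N2O mixes linearly and respects the tracer ceiling", {
  # nothing produced: the atmospheric background passes through
  r <- simulate_n2o(pool_at = 10, produced_ppm = 0)
  expect_equal(r$conc_ppm, 0.33)
  expect_equal(r$atpct_15N, 0.37)
  # hand-computed weighted mean
  r <- simulate_n2o(10, produced_ppm = 3, transfer_discount = 0.7)
  expect_equal(round(r$atpct_15N, 2), 6.34)
  expect_equal(r$conc_ppm, 3.33)
  # asymptote: overwhelming production carries the full pool enrichment
  r <- simulate_n2o(10, produced_ppm = 1e7, transfer_discount = 1)
  expect_equal(r$atpct_15N, 10, tolerance = 1e-6)
  withr::with_seed(41, {
    r <- simulate_n2o(pool_at = runif(200, 1, 15),
                      produced_ppm = runif(200, 0, 100),
                      transfer_discount = runif(200))
    expect_true(all(r$atpct_15N <= r$max_at))
  })
})
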