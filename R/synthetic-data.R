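#' Configuration for a simulated pool-dilution assay
#'
#' Bundles the true rates and the measurement model for one forward
#' simulation of a 15N pool-dilution incubation. Gross production and
#' consumption are constant (zero-order) over the assay window, the
#' assumption under which the rate equations are exact.
#'
#' @param gp_true,gc_true true gross production/consumption rates,
#'   mg N (kg DM day)^-1, both >= 0.
#' @param c0 pool size immediately after tracer addition, mg N per kg DM.
#' @param at0 pool enrichment immediately after tracer addition, atom
#'   percent 15N; must exceed `bg_at`.
#' @param bg_at natural-abundance background, atom percent 15N.
#' @param times_h sampling times in hours since tracer addition.
#' @param noise_conc_cv relative SD of the (lognormal, mean-preserving)
#'   measurement noise on concentrations.
#' @param noise_at_sd absolute SD in atom percent of the Gaussian
#'   measurement noise on enrichments, truncated to `[bg_at, 100]` for
#'   labeled records and `[0, 100]` for backgrounds.
#' @param blank_n_ug,blank_at reagent-blank model: ug N carried through the
#'   procedure and its enrichment. The blank N mixes into each labeled
#'   aliquot before "measurement", exactly what [blank_correct()] undoes.
#' @param aliquot_ug_per_conc ug N in the measured aliquot per unit of
#'   concentration (mg N per kg DM); default 1, i.e. an aliquot equivalent
#'   to 1 g DM.
#' @param seed integer seed making the simulation reproducible; `NULL` uses
#'   the current RNG state.
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_pool()]
#' @export
sim_config <- function(gp_true, gc_true, c0, at0,
                       bg_at = natural_abundance_atpct(),
                       times_h = c(4, 24),
                       noise_conc_cv = 0, noise_at_sd = 0,
                       blank_n_ug = 2, blank_at = bg_at,
                       aliquot_ug_per_conc = 1, seed = NULL) {
  stopifnot(gp_true >= 0, gc_true >= 0, c0 > 0,
            at0 > bg_at, bg_at >= 0, bg_at <= 100,
            length(times_h) >= 1, all(times_h > 0),
            noise_conc_cv >= 0, noise_at_sd >= 0,
            blank_n_ug >= 0, aliquot_ug_per_conc > 0)
  structure(list(gp_true = gp_true, gc_true = gc_true, c0 = c0, at0 = at0,
                 bg_at = bg_at, times_h = sort(times_h),
                 noise_conc_cv = noise_conc_cv, noise_at_sd = noise_at_sd,
                 blank_n_ug = blank_n_ug, blank_at = blank_at,
                 aliquot_ug_per_conc = aliquot_ug_per_conc, seed = seed),
            class = "sim_config")
}

#' Closed-form trajectory of the constant-rate two-pool model
#'
#' With constant gross production GP (entering at background enrichment) and
#' constant gross consumption GC (leaving at the prevailing enrichment), the
#' pool follows \eqn{C(t) = C0 + (GP - GC) t} and the excess enrichment
#' \deqn{APE(t) = APE0 (C(t)/C0)^{-GP/(GP-GC)}}
#' with the limit \eqn{APE0 exp(-GP t / C0)} when GP = GC. Applying the rate
#' equations to any two points of this trajectory returns GP and GC exactly.
#'
#' @param t_day times in days since tracer addition (>= 0).
#' @param gp,gc true gross rates, mg N (kg DM day)^-1.
#' @param c0 initial pool, mg N per kg DM.
#' @param at0 initial enrichment, atom percent 15N.
#' @param bg_at background enrichment, atom percent 15N.
#' @return A tibble with `t_day`, `conc`, `ape`, `at` (= `bg_at + ape`).
#' @examples
#' pool_trajectory(c(4, 24) / 24, gp = 12, gc = 30, c0 = 110, at0 = 9.24)
#' @export
pool_trajectory <- function(t_day, gp, gc, c0, at0,
                            bg_at = natural_abundance_atpct()) {
  stopifnot(all(t_day >= 0), gp >= 0, gc >= 0, c0 > 0, at0 > bg_at)
  m <- gp - gc
  conc <- c0 + m * t_day
  if (any(conc <= 0)) {
    stop("pool exhausted within the sampled window (C(t) <= 0); ",
         "shorten the window or reduce net consumption")
  }
  ape0 <- at0 - bg_at
  ape <- if (abs(m) < 1e-12 * max(gp, gc, 1)) {
    ape0 * exp(-gp * t_day / c0)
  } else {
    ape0 * (conc / c0)^(-gp / m)
  }
  tibble::tibble(t_day = t_day, conc = conc, ape = ape, at = bg_at + ape)
}

# Inverse-CDF truncated normal; deterministic under the active RNG stream.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, length.out = n))
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

# Mean-preserving lognormal multiplicative noise with relative SD = cv.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Forward-simulate one pool-dilution incubation
#'
#' Generates the records an analyst would obtain from one tracer addition:
#' labeled incubations terminated at each of `times_h`, an unlabeled
#' background reference, and the procedural blank. The noiseless trajectory
#' follows [pool_trajectory()]; blank N is mixed into each labeled aliquot
#' (so that [blank_correct()] inverts it exactly), then measurement noise is
#' applied. With all noise at zero, [compute_rates()] on the output recovers
#' the true rates to machine precision.
#'
#' @param cfg a [sim_config()].
#' @param reactor_id,group,day,assay,tracer_mode,replicate metadata stamped
#'   onto the generated records.
#' @return A list of class `"ipd_simulation"` with tibbles `incubations`
#'   (labeled records plus one background record, schema as consumed by
#'   [ipd_rates()]), `blanks` (one row: `at_blk`, `n_blk_ug`) and `truth`
#'   (the generating parameters).
#' @examples
#' sim <- simulate_pool(sim_config(gp_true = 12, gc_true = 30,
#'                                 c0 = 110, at0 = 9.24, seed = 1))
#' sim$incubations
#' @export
simulate_pool <- function(cfg, reactor_id = "R1", group = "aerobic",
                          day = 0L, assay = "mineralization",
                          tracer_mode = "pool", replicate = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  run <- function() {
    traj <- pool_trajectory(cfg$times_h / 24, cfg$gp_true, cfg$gc_true,
                            cfg$c0, cfg$at0, cfg$bg_at)
    n_true <- traj$conc * cfg$aliquot_ug_per_conc
    # reagent blank mixes into the measured aliquot
    n_tot <- n_true + cfg$blank_n_ug
    at_mix <- (traj$at * n_true + cfg$blank_at * cfg$blank_n_ug) / n_tot
    nt <- length(cfg$times_h)
    conc_obs <- traj$conc * rlnorm_cv(nt, cfg$noise_conc_cv)
    at_obs <- rnorm_trunc(nt, at_mix, cfg$noise_at_sd, cfg$bg_at, 100)

    lab <- tibble::tibble(
      sample_id = sprintf("%s-d%03d-%s-%s-r%d-t%gh", reactor_id, day,
                          substr(assay, 1, 3), tracer_mode, replicate,
                          cfg$times_h),
      reactor_id = reactor_id, group = group, day = as.integer(day),
      assay = assay, tracer_mode = tracer_mode,
      replicate = as.integer(replicate), time_h = cfg$times_h,
      conc_mgN_per_kgDM = conc_obs, atpct_15N = at_obs,
      n_total_ug = n_tot
    )
    # unlabeled reference: no tracer, not blank corrected downstream
    bg_at_obs <- rnorm_trunc(1, cfg$bg_at, cfg$noise_at_sd, 0, 100)
    bg_conc <- cfg$c0 * rlnorm_cv(1, cfg$noise_conc_cv)
    bg <- tibble::tibble(
      sample_id = sprintf("%s-d%03d-%s-bg-r%d", reactor_id, day,
                          substr(assay, 1, 3), replicate),
      reactor_id = reactor_id, group = group, day = as.integer(day),
      assay = assay, tracer_mode = "none",
      replicate = as.integer(replicate), time_h = max(cfg$times_h),
      conc_mgN_per_kgDM = bg_conc, atpct_15N = bg_at_obs,
      n_total_ug = bg_conc * cfg$aliquot_ug_per_conc
    )
    list(incubations = dplyr::bind_rows(lab, bg))
  }
  out <- if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
  structure(
    list(incubations = out$incubations,
         blanks = tibble::tibble(at_blk = cfg$blank_at,
                                 n_blk_ug = cfg$blank_n_ug),
         truth = tibble::tibble(reactor_id = reactor_id, group = group,
                                day = as.integer(day), assay = assay,
                                tracer_mode = tracer_mode,
                                replicate = as.integer(replicate),
                                gp_true = cfg$gp_true, gc_true = cfg$gc_true,
                                c0 = cfg$c0, at0 = cfg$at0,
                                bg_at = cfg$bg_at,
                                seed = cfg$seed %||% NA_integer_)),
    class = "ipd_simulation")
}

#' Simulate a headspace N2O measurement
#'
#' Mixes newly produced N2O (carrying the enrichment of its source pool,
#' optionally discounted for incomplete transfer of label through the
#' producing pathway) into the atmospheric background. The mixture
#' enrichment can never exceed the source-pool enrichment, which is the
#' physical ceiling used by [screen_n2o()].
#'
#' @param pool_at enrichment of the source (tracer-amended) pool, atom
#'   percent 15N; also the achievable maximum reported as `max_at`.
#' @param produced_ppm N2O newly produced during the incubation, ppm.
#' @param bg_ppm,bg_at atmospheric background N2O concentration (default
#'   0.33 ppm) and enrichment (default 0.37 at%).
#' @param transfer_discount fraction in `[0, 1]` of the pool enrichment that
#'   reaches the N2O actually produced.
#' @return A tibble with `conc_ppm`, `atpct_15N`, `max_at`.
#' @examples
#' simulate_n2o(pool_at = 10, produced_ppm = 3, transfer_discount = 0.7)
#' @export
simulate_n2o <- function(pool_at, produced_ppm, bg_ppm = 0.33, bg_at = 0.37,
                         transfer_discount = 1) {
  stopifnot(all(produced_ppm >= 0), all(bg_ppm >= 0),
            all(transfer_discount >= 0), all(transfer_discount <= 1))
  check_atpct(pool_at, "pool_at")
  check_atpct(bg_at, "bg_at")
  conc <- bg_ppm + produced_ppm
  at <- (bg_ppm * bg_at + produced_ppm * pool_at * transfer_discount) / conc
  tibble::tibble(conc_ppm = conc, atpct_15N = at, max_at = pool_at)
}

#' Default study design for the synthetic campaign
#'
#' One row per (group, day, assay) cell of a two-year landfill-reactor style
#' campaign: three operational groups (aerobic, aerobic-anaerobic after
#' aeration stops at day 355, anaerobic), five sampling days, and both
#' assays (ammonium for mineralization, nitrate for nitrification). Native
#' pools and rate magnitudes echo the published scale of such systems: large
#' ammonium pools (~1000 mg N per kg DM) with fluxes of tens to hundreds of
#' mg N (kg DM day)^-1 early and under anaeroby, small pools (tens) with
#' fluxes of a few to ~35 under stable aeration, and nitrate pools of
#' 5-55 mg N per kg DM with nitrification fluxes up to ~30. `n2o_ppm` is the
#' N2O produced into the headspace (mostly zero; a large pulse around the
#' start of aeration).
#'
#' @return A tibble with columns `group`, `day`, `assay`, `native_pool`,
#'   `gp_true`, `gc_true`, `n2o_ppm`.
#' @export
default_study_cells <- function() {
  m <- "mineralization"; n <- "nitrification"
  ae <- "aerobic"; aa <- "aerobic_anaerobic"; an <- "anaerobic"
  tibble::tribble(
    ~group, ~day, ~assay, ~native_pool, ~gp_true, ~gc_true, ~n2o_ppm,
    ae,   0L, m,  927.0, 480.0, 500.0,  0,
    ae,  54L, m,  923.0,  50.5, 100.0, 75,
    ae, 110L, m,   40.0,   3.7,  35.7,  3,
    ae, 355L, m,   20.8,  16.4,  27.0,  0,
    ae, 753L, m,   11.1,   4.7,   6.8,  0,
    aa,   0L, m, 1040.0, 400.0, 450.0,  0,
    aa,  54L, m, 1037.0,  50.0, 120.0, 60,
    aa, 110L, m,   40.0,   5.0,  30.0,  2,
    aa, 355L, m,   21.8,  14.4,  25.0,  0,
    aa, 753L, m,  151.5,  10.1,  20.1,  0,
    an,   0L, m, 1035.0, 158.0, 134.2,  0,
    an, 753L, m,  880.6,  50.0,  50.0,  0,
    ae,   0L, n,   26.6,   3.0,  20.0,  0,
    ae,  54L, n,   11.7,  18.7,  30.0,  2,
    ae, 110L, n,   25.6,   7.6,  25.0,  1,
    ae, 355L, n,   13.4,  15.8,  20.0,  0,
    ae, 753L, n,   53.6,   5.8,  15.2,  0,
    aa,   0L, n,   28.4,  25.0,  35.0,  0,
    aa,  54L, n,   12.6,  18.7,  30.0,  2,
    aa, 110L, n,   20.9,   7.6,  25.0,  1,
    aa, 355L, n,   41.8,  15.8,  20.0,  0,
    aa, 753L, n,    6.1,  15.8,  28.5,  0,
    an,   0L, n,   27.2,  20.0,  30.0,  0,
    an, 753L, n,    6.2,   0.5,   0.6,  0
  )
}

#' Scenario for a simulated multi-group campaign
#'
#' Couples a design table (see [default_study_cells()]) with the replication
#' structure and noise model of the campaign.
#'
#' @param cells design tibble with columns `group`, `day`, `assay`,
#'   `native_pool`, `gp_true`, `gc_true` and optionally `n2o_ppm`.
#' @param n_reactors replicate reactors per group (default 3).
#' @param reactor_cv lognormal between-reactor relative SD on the true rates.
#' @param pool_cv lognormal between-reactor relative SD on native pools.
#' @param noise_conc_cv,noise_at_sd,blank_n_ug,bg_at measurement model,
#'   passed to [sim_config()].
#' @param pool_mode_min native pool (mg N per kg DM) above which the tracer
#'   is added in pool mode; smaller pools are spiked.
#' @param spike_floor,label_enrichment,target_fraction passed to
#'   [plan_tracer()].
#' @param n2o_transfer_discount label-transfer discount for headspace N2O.
#' @param exclusion_fraction fraction of incubation pairs whose enrichments
#'   are swapped in time, guaranteeing an APE rise; exercises the exclusion
#'   path of the rate pipeline.
#' @return A list of class `"study_scenario"`.
#' @seealso [simulate_study()]
#' @export
study_scenario <- function(cells = default_study_cells(), n_reactors = 3,
                           reactor_cv = 0.3, pool_cv = 0.05,
                           noise_conc_cv = 0.05, noise_at_sd = 0.1,
                           blank_n_ug = 2,
                           bg_at = natural_abundance_atpct(),
                           pool_mode_min = 50, spike_floor = 15,
                           label_enrichment = 98, target_fraction = 0.1,
                           n2o_transfer_discount = 0.7,
                           exclusion_fraction = 0) {
  req <- c("group", "day", "assay", "native_pool", "gp_true", "gc_true")
  if (!all(req %in% names(cells))) {
    stop("`cells` must have columns ", paste(req, collapse = ", "))
  }
  if (!"n2o_ppm" %in% names(cells)) cells$n2o_ppm <- 0
  stopifnot(n_reactors >= 1, reactor_cv >= 0, pool_cv >= 0,
            exclusion_fraction >= 0, exclusion_fraction <= 1)
  structure(list(cells = cells, n_reactors = n_reactors,
                 reactor_cv = reactor_cv, pool_cv = pool_cv,
                 noise_conc_cv = noise_conc_cv, noise_at_sd = noise_at_sd,
                 blank_n_ug = blank_n_ug, bg_at = bg_at,
                 pool_mode_min = pool_mode_min, spike_floor = spike_floor,
                 label_enrichment = label_enrichment,
                 target_fraction = target_fraction,
                 n2o_transfer_discount = n2o_transfer_discount,
                 exclusion_fraction = exclusion_fraction),
            class = "study_scenario")
}

#' Forward-simulate a full sampling campaign
#'
#' Expands every design cell over the replicate reactors, plans the tracer
#' addition per reactor (pool or spike mode by pool size), forward-simulates
#' each incubation with [simulate_pool()], and generates matching headspace
#' N2O records. Reactor-level biological variability is applied as lognormal
#' multipliers on the true rates; rates are capped where needed so the pool
#' is never exhausted within the assay window (the capped value is what the
#' truth table reports). A configurable fraction of pairs is made invalid by
#' swapping the two enrichments, to exercise exclusion handling downstream.
#'
#' The master `seed` drives a deterministic per-incubation sub-seed stream
#' (recorded in `truth$seed`), so output is reproducible record-by-record.
#'
#' @param scenario a [study_scenario()].
#' @param seed master integer seed; `NULL` uses the current RNG state.
#' @return A list of class `"ipd_study"` with tibbles `incubations`,
#'   `blanks`, `n2o` and `truth` (per reactor x cell: simulated true rates,
#'   initial conditions, tracer mode, `forced_invalid`, sub-seed).
#' @examples
#' study <- simulate_study(study_scenario(), seed = 42)
#' dplyr::count(study$incubations, .data$assay, .data$tracer_mode)
#' @export
simulate_study <- function(scenario = study_scenario(), seed = NULL) {
  stopifnot(inherits(scenario, "study_scenario"))
  sc <- scenario
  units <- tidyr::expand_grid(sc$cells,
                              reactor = seq_len(sc$n_reactors)) %>%
    dplyr::mutate(reactor_id = sprintf("%s-R%d", abbreviate_group(.data$group),
                                       .data$reactor))
  n_units <- nrow(units)
  draw <- function() {
    list(sub = sample.int(.Machine$integer.max - 1L, n_units),
         gp_mult = rlnorm_cv(n_units, sc$reactor_cv),
         gc_mult = rlnorm_cv(n_units, sc$reactor_cv),
         pool_mult = rlnorm_cv(n_units, sc$pool_cv),
         n2o_mult = rlnorm_cv(n_units, 0.2),
         forced = runif(n_units) < sc$exclusion_fraction)
  }
  rng <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  t_max <- 1  # assay window, days
  sims <- purrr::pmap(
    list(i = seq_len(n_units)),
    function(i) {
      u <- units[i, ]
      pool <- u$native_pool * rng$pool_mult[i]
      mode <- if (pool >= sc$pool_mode_min) "pool" else "spike"
      plan <- plan_tracer(pool, mode,
                          target_fraction = sc$target_fraction,
                          bg_at = sc$bg_at,
                          label_enrichment = sc$label_enrichment,
                          spike_floor = sc$spike_floor)
      gp <- u$gp_true * rng$gp_mult[i]
      gc <- u$gc_true * rng$gc_mult[i]
      # keep the assay physically feasible: >= 5% of the pool must survive
      gc_cap <- gp + 0.95 * plan$predicted_pool / t_max
      gc <- min(gc, gc_cap)
      cfg <- sim_config(gp, gc, c0 = plan$predicted_pool,
                        at0 = plan$predicted_at0, bg_at = sc$bg_at,
                        noise_conc_cv = sc$noise_conc_cv,
                        noise_at_sd = sc$noise_at_sd,
                        blank_n_ug = sc$blank_n_ug, blank_at = sc$bg_at,
                        seed = rng$sub[i])
      sim <- simulate_pool(cfg, reactor_id = u$reactor_id, group = u$group,
                           day = u$day, assay = u$assay, tracer_mode = mode)
      inc <- sim$incubations
      if (rng$forced[i]) {
        lab <- which(inc$tracer_mode != "none")
        inc$atpct_15N[lab] <- rev(inc$atpct_15N[lab])
      }
      n2o <- simulate_n2o(plan$predicted_at0,
                          produced_ppm = u$n2o_ppm * rng$n2o_mult[i],
                          transfer_discount = sc$n2o_transfer_discount) %>%
        dplyr::mutate(sample_id = sprintf("%s-d%03d-%s-n2o", u$reactor_id,
                                          u$day, substr(u$assay, 1, 3)),
                      assay = u$assay, group = u$group, day = u$day,
                      .before = 1)
      truth <- sim$truth %>%
        dplyr::mutate(native_pool = pool, forced_invalid = rng$forced[i])
      list(incubations = inc, n2o = n2o, truth = truth)
    })

  structure(
    list(incubations = purrr::map_dfr(sims, "incubations"),
         blanks = tibble::tibble(at_blk = sc$bg_at, n_blk_ug = sc$blank_n_ug),
         n2o = purrr::map_dfr(sims, "n2o"),
         truth = purrr::map_dfr(sims, "truth")),
    class = "ipd_study")
}

abbreviate_group <- function(group) {
  vapply(strsplit(group, "_", fixed = TRUE),
         function(p) paste(toupper(substr(p, 1, 2)), collapse = ""),
         character(1))
}
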