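#' Analysis configuration
#'
#' Central knobs of the rate pipeline. Defaults follow common practice for
#' 15N pool-dilution assays; every value can be overridden here or from a
#' YAML file via [read_ipd_config()].
#'
#' @param background_atpct fallback background enrichment (atom percent)
#'   used when a (reactor, day, assay) has no unlabeled reference record.
#' @param conc_tol relative concentration-equality tolerance, see
#'   [gross_production()].
#' @param ape_tol minimum APE decline (atom percent) for a pair to be
#'   considered valid, see [compute_rates()].
#' @param spike_floor,label_enrichment,target_fraction tracer-planning
#'   defaults, see [plan_tracer()].
#' @param alpha significance level for Tukey comparisons (default 0.05,
#'   i.e. 95% family-wise confidence).
#' @param n2o_bg_ppm,n2o_bg_at,n2o_ppm_tol,n2o_at_tol N2O screening
#'   defaults, see [screen_n2o()].
#' @param seed integer seed recorded in the run log (the analysis itself is
#'   deterministic; the seed matters when the input is simulated).
#' @return A list of class `"ipd_config"`.
#' @export
ipd_config <- function(background_atpct = natural_abundance_atpct(),
                       conc_tol = 1e-6, ape_tol = 1e-6,
                       spike_floor = 15, label_enrichment = 98,
                       target_fraction = 0.1, alpha = 0.05,
                       n2o_bg_ppm = 0.33, n2o_bg_at = 0.37,
                       n2o_ppm_tol = 0.05, n2o_at_tol = 0.1,
                       seed = NULL) {
  structure(list(background_atpct = background_atpct, conc_tol = conc_tol,
                 ape_tol = ape_tol, spike_floor = spike_floor,
                 label_enrichment = label_enrichment,
                 target_fraction = target_fraction, alpha = alpha,
                 n2o_bg_ppm = n2o_bg_ppm, n2o_bg_at = n2o_bg_at,
                 n2o_ppm_tol = n2o_ppm_tol, n2o_at_tol = n2o_at_tol,
                 seed = seed),
            class = "ipd_config")
}

#' Read an analysis configuration from YAML
#'
#' Keys present in the file override the [ipd_config()] defaults; unknown
#' keys raise an error to catch typos.
#'
#' @param path path to a YAML file.
#' @return An `"ipd_config"` list.
#' @export
read_ipd_config <- function(path) {
  vals <- yaml::read_yaml(path)
  defaults <- ipd_config()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(ipd_config, vals)
}

read_table_or_df <- function(x, col_types = NULL) {
  if (is.character(x) && length(x) == 1L) {
    x <- readr::read_csv(x, col_types = col_types, show_col_types = FALSE)
  }
  tibble::as_tibble(x)
}

incubation_cols <- function() {
  readr::cols(sample_id = "c", reactor_id = "c", group = "c", day = "i",
              assay = "c", tracer_mode = "c", replicate = "i",
              time_h = "d", conc_mgN_per_kgDM = "d", atpct_15N = "d",
              n_total_ug = "d")
}

#' Gross rates for every incubation pair in a table
#'
#' Applies [compute_rates()] across a campaign table: records are paired
#' within (reactor, day, assay, replicate); the unlabeled reference of the
#' same reactor/day/assay supplies the background enrichment (falling back
#' to `config$background_atpct` when absent); blanks are averaged into a
#' single procedural blank. Pairs that cannot be formed or whose enrichment
#' fails to decline are returned with `valid = FALSE` and a reason, never
#' dropped silently.
#'
#' @param incubations data frame or CSV path with columns `sample_id`,
#'   `reactor_id`, `group`, `day`, `assay`, `tracer_mode`, `replicate`,
#'   `time_h`, `conc_mgN_per_kgDM`, `atpct_15N`, `n_total_ug`.
#' @param blanks data frame or CSV path with columns `at_blk`, `n_blk_ug`;
#'   `NULL` for no blank correction.
#' @param config an [ipd_config()].
#' @return A tibble, one row per pair: metadata, `sample_id_t1/t2`, `gp`,
#'   `gc`, `net` (mg N (kg DM day)^-1), `ape_t1`, `ape_t2`, `valid`,
#'   `exclusion_reason`.
#' @examples
#' sim <- simulate_pool(sim_config(gp_true = 12, gc_true = 30,
#'                                 c0 = 110, at0 = 9.24, seed = 7))
#' ipd_rates(sim$incubations, sim$blanks)
#' @export
ipd_rates <- function(incubations, blanks = NULL, config = ipd_config()) {
  inc <- read_table_or_df(incubations, incubation_cols())
  req <- c("reactor_id", "group", "day", "assay", "tracer_mode", "replicate",
           "time_h", "conc_mgN_per_kgDM", "atpct_15N", "n_total_ug")
  if (!all(req %in% names(inc))) {
    stop("incubation table is missing columns: ",
         paste(setdiff(req, names(inc)), collapse = ", "))
  }
  if (!"sample_id" %in% names(inc)) inc$sample_id <- as.character(seq_len(nrow(inc)))
  blank <- if (is.null(blanks)) {
    list(at_blk = 0, n_blk_ug = 0)
  } else {
    b <- read_table_or_df(blanks, readr::cols(at_blk = "d", n_blk_ug = "d"))
    list(at_blk = mean(b$at_blk), n_blk_ug = mean(b$n_blk_ug))
  }

  backgrounds <- inc %>%
    dplyr::filter(.data$tracer_mode == "none") %>%
    dplyr::group_by(.data$reactor_id, .data$day, .data$assay) %>%
    dplyr::summarise(at_bg = mean(.data$atpct_15N), .groups = "drop")

  inc %>%
    dplyr::filter(.data$tracer_mode != "none") %>%
    dplyr::left_join(backgrounds, by = c("reactor_id", "day", "assay")) %>%
    dplyr::mutate(at_bg = dplyr::coalesce(.data$at_bg, config$background_atpct)) %>%
    dplyr::group_by(.data$group, .data$reactor_id, .data$day, .data$assay,
                    .data$tracer_mode, .data$replicate) %>%
    dplyr::arrange(.data$time_h, .by_group = TRUE) %>%
    dplyr::group_modify(function(d, key) {
      if (nrow(d) != 2L) {
        return(tibble::tibble(
          sample_id_t1 = d$sample_id[1], sample_id_t2 = NA_character_,
          gp = NA_real_, gc = NA_real_, net = NA_real_,
          ape_t1 = NA_real_, ape_t2 = NA_real_,
          valid = FALSE,
          exclusion_reason = sprintf("unpaired records (%d time points)", nrow(d))))
      }
      as_rec <- function(row) list(conc = row$conc_mgN_per_kgDM,
                                   at_meas = row$atpct_15N,
                                   n_total_ug = row$n_total_ug,
                                   time_h = row$time_h)
      compute_rates(as_rec(d[1, ]), as_rec(d[2, ]),
                    background = list(at_meas = d$at_bg[1],
                                      tracer_mode = "none"),
                    blank = blank,
                    conc_tol = config$conc_tol, ape_tol = config$ape_tol) %>%
        dplyr::mutate(sample_id_t1 = d$sample_id[1],
                      sample_id_t2 = d$sample_id[2], .before = 1)
    }) %>%
    dplyr::ungroup()
}

#' Group-level rate summaries
#'
#' Aggregates per-pair rates to the experiment's reporting unit. Technical
#' replicates are first averaged within each reactor, then reactors are
#' summarized per cell (default: group x day x assay) as mean and standard
#' error (1 SE = sd / sqrt(n)). Cells with a single valid reactor report
#' their mean with the SE flagged undefined rather than a fabricated zero;
#' excluded pairs are counted per cell.
#'
#' @param rates output of [ipd_rates()].
#' @param by cell-defining columns (default `c("group", "day", "assay")`).
#' @return A tibble of class `"ipd_summary"`, long over `rate`
#'   (gp / gc / net): `n`, `mean`, `se`, `se_undefined`, `excluded_count`.
#' @export
summarize_rates <- function(rates, by = c("group", "day", "assay")) {
  stopifnot(all(by %in% names(rates)), "reactor_id" %in% names(rates))
  excl <- rates %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::summarise(excluded_count = sum(!.data$valid), .groups = "drop")
  out <- rates %>%
    dplyr::filter(.data$valid) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "reactor_id")))) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(c("gp", "gc", "net")), mean),
                     .groups = "drop") %>%
    tidyr::pivot_longer(dplyr::all_of(c("gp", "gc", "net")),
                        names_to = "rate", values_to = "value") %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "rate")))) %>%
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     se = ifelse(dplyr::n() < 2, NA_real_,
                                 sd(.data$value) / sqrt(dplyr::n())),
                     .groups = "drop") %>%
    dplyr::mutate(se_undefined = is.na(.data$se)) %>%
    dplyr::left_join(excl, by = by)
  class(out) <- c("ipd_summary", class(out))
  out
}

#' Net rate from gross means
#'
#' Net mineralization (or nitrification) is gross production minus gross
#' consumption of the pool; negative values indicate net removal.
#'
#' @param gp_mean,gc_mean gross production / consumption,
#'   mg N (kg DM day)^-1.
#' @return Net rate, same units.
#' @examples
#' net_from_gross(3.7, 35.7)  # -32
#' @export
net_from_gross <- function(gp_mean, gc_mean) gp_mean - gc_mean

#' One-way ANOVA with Tukey HSD comparisons
#'
#' Tests for differences among cell means (one factor, possibly formed by
#' crossing several grouping columns) and, when the omnibus test is
#' defensible, performs all pairwise comparisons controlled at family-wise
#' level `alpha` via the studentized-range distribution. With fewer than
#' two cells holding at least two values each, a structured skip is
#' returned instead of an error, so pipelines over sparse designs keep
#' running.
#'
#' @param data data frame holding the response and grouping columns.
#' @param value response column (unquoted or string).
#' @param by character vector of grouping columns; their crossing defines
#'   the cells.
#' @param alpha family-wise error rate for the comparisons (default 0.05).
#' @return An object of class `"ipd_anova"`; see [tidy.ipd_anova()] and
#'   [glance.ipd_anova()].
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' fit <- anova_tukey(df, y, by = "g")
#' glance(fit)
#' tidy(fit)
#' @export
anova_tukey <- function(data, value, by = "group", alpha = 0.05) {
  v <- rlang::as_name(rlang::ensym(value))
  stopifnot(v %in% names(data), all(by %in% names(data)),
            alpha > 0, alpha < 1)
  cells <- do.call(paste, c(lapply(by, function(b) data[[b]]), sep = ":"))
  df <- data.frame(value = data[[v]], cell = cells)
  df <- df[!is.na(df$value), , drop = FALSE]
  counts <- table(df$cell)
  skip <- function(reason) {
    structure(list(skipped = TRUE, reason = reason, alpha = alpha),
              class = "ipd_anova")
  }
  if (sum(counts >= 2) < 2) {
    return(skip("fewer than 2 cells with >= 2 values; no statistical evaluation possible"))
  }
  df <- df[df$cell %in% names(counts)[counts >= 2], , drop = FALSE]
  df$cell <- factor(df$cell)
  fit <- aov(value ~ cell, data = df)
  tab <- summary(fit)[[1]]
  msw <- tab[["Mean Sq"]][2]
  f_stat <- tab[["F value"]][1]
  p_val <- tab[["Pr(>F)"]][1]
  if (sd(df$value) <= sqrt(.Machine$double.eps) * max(1, abs(mean(df$value)))) {
    # response is constant: no between-cell variance to explain
    f_stat <- 0
    p_val <- 1
  }
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$cell
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  n_i <- table(df$cell)
  k <- nlevels(df$cell)
  df_w <- tab[["Df"]][2]
  comp <- tibble::tibble(
    cell_a = vapply(pairs, `[`, "", 1L),
    cell_b = vapply(pairs, `[`, "", 2L),
    estimate = unname(tk[, "diff"]),
    conf.low = unname(tk[, "lwr"]), conf.high = unname(tk[, "upr"]),
    q = unname(abs(tk[, "diff"])) /
      sqrt(msw / 2 * unname(1 / n_i[vapply(pairs, `[`, "", 1L)] +
                              1 / n_i[vapply(pairs, `[`, "", 2L)])),
    adj.p.value = unname(tk[, "p adj"]),
    significant = unname(!is.na(tk[, "p adj"]) & tk[, "p adj"] < alpha)
  )
  structure(list(skipped = FALSE, reason = "",
                 f_statistic = f_stat, p_value = p_val,
                 df_between = tab[["Df"]][1], df_within = df_w,
                 ms_within = msw, k = k, n = nrow(df),
                 alpha = alpha, comparisons = comp),
            class = "ipd_anova")
}

#' @export
print.ipd_anova <- function(x, ...) {
  if (x$skipped) {
    cat("One-way ANOVA: skipped (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  cat(sprintf("Tukey HSD at %d%% family-wise confidence: %d of %d pairs significant\n",
              round(100 * (1 - x$alpha)), sum(x$comparisons$significant),
              nrow(x$comparisons)))
  invisible(x)
}

#' Tidy Tukey comparisons from an `ipd_anova`
#'
#' @param x an object from [anova_tukey()].
#' @param ... unused.
#' @return A tibble of pairwise comparisons (`cell_a`, `cell_b`,
#'   `estimate`, confidence bounds, studentized range `q`, `adj.p.value`,
#'   `significant`); zero rows if the test was skipped.
#' @method tidy ipd_anova
#' @export
tidy.ipd_anova <- function(x, ...) {
  if (x$skipped) {
    return(tibble::tibble(cell_a = character(), cell_b = character(),
                          estimate = double(), conf.low = double(),
                          conf.high = double(), q = double(),
                          adj.p.value = double(), significant = logical()))
  }
  x$comparisons
}

#' One-row summary of an `ipd_anova`
#'
#' @inheritParams tidy.ipd_anova
#' @return A one-row tibble: `statistic` (F), `p.value`, `df`,
#'   `df.residual`, `k`, `nobs`, `skipped`, `reason`.
#' @method glance ipd_anova
#' @export
glance.ipd_anova <- function(x, ...) {
  if (x$skipped) {
    return(tibble::tibble(statistic = NA_real_, p.value = NA_real_,
                          df = NA_integer_, df.residual = NA_integer_,
                          k = NA_integer_, nobs = NA_integer_,
                          skipped = TRUE, reason = x$reason))
  }
  tibble::tibble(statistic = x$f_statistic, p.value = x$p_value,
                 df = x$df_between, df.residual = x$df_within,
                 k = x$k, nobs = x$n, skipped = FALSE, reason = "")
}

#' Run the full rate pipeline
#'
#' End-to-end orchestration: read the incubation, blank and (optionally)
#' N2O tables, compute per-pair gross rates, collect exclusions, summarize
#' by group x day x assay, run one-way ANOVA + Tukey HSD across
#' (group, day) cells for each assay and rate, screen the N2O records, and
#' assemble a run log carrying a configuration hash so outputs are
#' traceable. Given identical inputs and configuration the result is
#' identical, including on disk via [write_ipd_results()].
#'
#' @param incubations,blanks data frames or CSV paths, see [ipd_rates()].
#' @param n2o optional data frame or CSV path with columns `sample_id`,
#'   `assay`, `group`, `day`, `conc_ppm`, `atpct_15N`, `max_at`.
#' @param config an [ipd_config()].
#' @return A list of class `"ipd_run"`: `rates`, `summaries`, `exclusions`,
#'   `n2o_screen`, `anova` (list of [anova_tukey()] fits keyed
#'   `assay:rate`), `anova_glance`, `log`, `config`.
#' @examples
#' study <- simulate_study(study_scenario(), seed = 42)
#' run <- run_pipeline(study$incubations, study$blanks, study$n2o,
#'                     config = ipd_config(seed = 42))
#' run$summaries
#' @export
run_pipeline <- function(incubations, blanks = NULL, n2o = NULL,
                         config = ipd_config()) {
  stopifnot(inherits(config, "ipd_config"))
  rates <- ipd_rates(incubations, blanks, config)
  summaries <- summarize_rates(rates)
  exclusions <- rates %>%
    dplyr::filter(!.data$valid) %>%
    dplyr::select(dplyr::all_of(c("group", "reactor_id", "day", "assay",
                                  "replicate", "sample_id_t1", "sample_id_t2",
                                  "exclusion_reason")))
  n2o_screen <- if (!is.null(n2o)) {
    screen_n2o(read_table_or_df(n2o),
               bg_ppm = config$n2o_bg_ppm, bg_at = config$n2o_bg_at,
               ppm_tol = config$n2o_ppm_tol, at_tol = config$n2o_at_tol)
  }
  valid <- dplyr::filter(rates, .data$valid)
  combos <- tidyr::expand_grid(assay = unique(valid$assay),
                               rate = c("gp", "gc", "net"))
  fits <- purrr::pmap(combos, function(assay, rate) {
    d <- valid[valid$assay == assay, ]
    anova_tukey(stats::setNames(d, sub(paste0("^", rate, "$"), "value",
                                       names(d))),
                value, by = c("group", "day"), alpha = config$alpha)
  })
  names(fits) <- paste(combos$assay, combos$rate, sep = ":")
  anova_glance <- purrr::map_dfr(fits, glance, .id = "test")

  log <- tibble::tibble(
    key = c("config_hash", "seed", "n_pairs", "n_valid", "n_excluded",
            "n_n2o_records"),
    value = c(rlang::hash(unclass(config)),
              as.character(config$seed %||% NA),
              as.character(nrow(rates)), as.character(sum(rates$valid)),
              as.character(sum(!rates$valid)),
              as.character(if (is.null(n2o_screen)) 0L else nrow(n2o_screen))))
  structure(list(rates = rates, summaries = summaries,
                 exclusions = exclusions, n2o_screen = n2o_screen,
                 anova = fits, anova_glance = anova_glance,
                 log = log, config = config),
            class = "ipd_run")
}

#' @export
print.ipd_run <- function(x, ...) {
  cat("Isotope pool dilution run\n")
  cat(sprintf("  pairs: %s valid, %s excluded\n",
              sum(x$rates$valid), sum(!x$rates$valid)))
  cat(sprintf("  cells summarized: %d\n",
              nrow(dplyr::distinct(x$summaries,
                                   .data$group, .data$day, .data$assay))))
  if (!is.null(x$n2o_screen)) {
    cat(sprintf("  N2O records screened: %d (%d above ceiling)\n",
                nrow(x$n2o_screen), sum(x$n2o_screen$exceeds_ceiling)))
  }
  invisible(x)
}

#' Write pipeline results to CSV
#'
#' Emits `rates.csv`, `summaries.csv`, `exclusions.csv`, `n2o_screen.csv`
#' (when present), `anova.csv` and `run_log.csv` into `dir`. Numeric output
#' is written at full precision; rounding is left to the report layer.
#' Output is byte-identical for identical runs.
#'
#' @param run an [run_pipeline()] result.
#' @param dir output directory, created if needed.
#' @return Invisibly, a named character vector of file paths.
#' @export
write_ipd_results <- function(run, dir) {
  stopifnot(inherits(run, "ipd_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(rates = run$rates, summaries = run$summaries,
                 exclusions = run$exclusions, anova = run$anova_glance,
                 run_log = run$log)
  if (!is.null(run$n2o_screen)) tables$n2o_screen <- run$n2o_screen
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
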