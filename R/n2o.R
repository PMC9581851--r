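#' Enrichment of N2O as a percentage of the achievable maximum
#'
#' Headspace N2O formed from a tracer-amended pool can at most carry that
#' pool's enrichment; its measured enrichment is therefore usefully
#' expressed relative to that ceiling, rescaled so the natural-abundance
#' background maps to 0 and the ceiling to 100:
#' \deqn{100 (at - at(bg)) / (at(max) - at(bg))}
#'
#' @param at_pct measured N2O enrichment, atom percent 15N.
#' @param max_at achievable maximum: the enrichment added through the
#'   tracer substances (typically ~10 at%). Must exceed `bg_at`.
#' @param bg_at natural-abundance background, atom percent (default 0.37).
#' @return Percent of maximum achievable enrichment. Values outside
#'   `[0, 100]` (measurement above the ceiling or below background) are
#'   returned as-is with a warning.
#' @examples
#' percent_of_max(7.1, max_at = 10)  # ~69.9
#' @export
percent_of_max <- function(at_pct, max_at, bg_at = 0.37) {
  check_atpct(at_pct, "at_pct")
  if (any(max_at <= bg_at, na.rm = TRUE)) {
    stop("`max_at` must exceed `bg_at` (no enrichment headroom)")
  }
  out <- 100 * (at_pct - bg_at) / (max_at - bg_at)
  if (any(out < 0 | out > 100, na.rm = TRUE)) {
    warning("enrichment outside [background, maximum]; check tracer ceiling")
  }
  out
}

#' Plausibility screen for headspace N2O records
#'
#' Flags each record against three physical expectations: the enrichment
#' cannot exceed the tracer-derived ceiling (`exceeds_ceiling`); a vial with
#' no net N2O production sits at the atmospheric background in both
#' concentration and enrichment (`at_background`); and concentrations
#' clearly above background indicate net production during the incubation
#' (`net_production`).
#'
#' @param records data frame with columns `conc_ppm`, `atpct_15N`, `max_at`;
#'   any other columns (sample metadata) are carried through.
#' @param bg_ppm,bg_at atmospheric background (defaults 0.33 ppm, 0.37 at%).
#' @param ppm_tol,at_tol absolute tolerances for calling a record
#'   "at background" (defaults 0.05 ppm, 0.1 at%).
#' @return The input as a tibble with logical columns `exceeds_ceiling`,
#'   `at_background`, `net_production` and numeric `pct_of_max` appended.
#' @examples
#' screen_n2o(data.frame(conc_ppm = 0.30, atpct_15N = 0.41, max_at = 10))
#' @export
screen_n2o <- function(records, bg_ppm = 0.33, bg_at = 0.37,
                       ppm_tol = 0.05, at_tol = 0.1) {
  req <- c("conc_ppm", "atpct_15N", "max_at")
  if (!all(req %in% names(records))) {
    stop("`records` must have columns ", paste(req, collapse = ", "))
  }
  tibble::as_tibble(records) %>%
    dplyr::mutate(
      exceeds_ceiling = .data$atpct_15N > .data$max_at,
      at_background = abs(.data$conc_ppm - bg_ppm) <= ppm_tol &
        abs(.data$atpct_15N - bg_at) <= at_tol,
      net_production = .data$conc_ppm > bg_ppm + ppm_tol,
      pct_of_max = suppressWarnings(
        percent_of_max(.data$atpct_15N, .data$max_at, bg_at))
    )
}
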