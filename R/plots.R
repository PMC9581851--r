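#' Plot group-level rate summaries
#'
#' Mean +/- 1 SE per group over experiment time, faceted by assay and rate.
#'
#' @param object an `"ipd_summary"` from [summarize_rates()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ipd_summary
#' @export
autoplot.ipd_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$day, y = .data$mean,
                               colour = .data$group, group = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - dplyr::coalesce(.data$se, 0),
                   ymax = .data$mean + dplyr::coalesce(.data$se, 0)),
      position = ggplot2::position_dodge(width = 15)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 15),
                       alpha = 0.5) +
    ggplot2::facet_grid(rate ~ assay, scales = "free_y") +
    ggplot2::labs(x = "experiment day",
                  y = expression("rate, mg N (kg DM day)"^-1),
                  colour = "group")
}

#' Plot a simulated incubation
#'
#' Pool size and enrichment of the generated records over incubation time,
#' with the noiseless closed-form trajectory underneath.
#'
#' @param object an `"ipd_simulation"` from [simulate_pool()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ipd_simulation
#' @export
autoplot.ipd_simulation <- function(object, ...) {
  tr <- object$truth
  grid <- pool_trajectory(seq(0, max(object$incubations$time_h) / 24,
                              length.out = 100),
                          tr$gp_true, tr$gc_true, tr$c0, tr$at0, tr$bg_at)
  obs <- object$incubations %>%
    dplyr::filter(.data$tracer_mode != "none") %>%
    tidyr::pivot_longer(dplyr::all_of(c("conc_mgN_per_kgDM", "atpct_15N")),
                        names_to = "quantity", values_to = "value")
  model <- grid %>%
    dplyr::transmute(time_h = .data$t_day * 24,
                     conc_mgN_per_kgDM = .data$conc, atpct_15N = .data$at) %>%
    tidyr::pivot_longer(-dplyr::all_of("time_h"),
                        names_to = "quantity", values_to = "value")
  labs <- c(conc_mgN_per_kgDM = "pool, mg N/kg DM",
            atpct_15N = "at% 15N")
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line(data = model, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y",
                        labeller = ggplot2::as_labeller(labs)) +
    ggplot2::labs(x = "hours since tracer addition", y = NULL)
}

#' Plot N2O screening results
#'
#' Enrichment (as percent of the tracer-derived maximum) against headspace
#' concentration, with screening flags mapped to colour.
#'
#' @param screened output of [screen_n2o()].
#' @return A ggplot object.
#' @export
plot_n2o_screen <- function(screened) {
  df <- screened %>%
    dplyr::mutate(status = dplyr::case_when(
      .data$exceeds_ceiling ~ "exceeds ceiling",
      .data$net_production ~ "net production",
      .data$at_background ~ "at background",
      TRUE ~ "other"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc_ppm, y = .data$pct_of_max,
                                   colour = .data$status)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "headspace N2O, ppm",
                  y = "% of maximum achievable enrichment",
                  colour = NULL)
}
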