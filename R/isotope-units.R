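#' 15N/14N isotope ratio of atmospheric N2
#'
#' The reference ratio of the AIR standard against which \eqn{\delta^{15}N}
#' values are expressed. All conversion helpers take it as an argument so a
#' different reference can be substituted.
#'
#' @format A length-one numeric, 0.0036765.
#' @export
R15_AIR <- 0.0036765

#' Convert delta-15N to atom percent 15N
#'
#' \eqn{\delta^{15}N} expresses the per-mil deviation of a sample's
#' \eqn{^{15}N/^{14}N} ratio from the atmospheric-N2 standard:
#' \eqn{R = R_{std}(1 + \delta/1000)}. Atom percent is the share of heavy
#' atoms, \eqn{100 R/(1+R)}.
#'
#' @param delta delta-15N in per mil vs AIR. Must exceed -1000 (at -1000 the
#'   isotope ratio vanishes).
#' @param r_standard 15N/14N ratio of the reference; default [R15_AIR].
#' @return Atom percent 15N, in `[0, 100)`.
#' @examples
#' delta_to_atom_percent(0)     # natural abundance, ~0.3663 at%
#' delta_to_atom_percent(1000)  # doubled ratio, ~0.7299 at%
#' @seealso [atom_percent_to_delta()], [natural_abundance_atpct()]
#' @export
delta_to_atom_percent <- function(delta, r_standard = R15_AIR) {
  stopifnot(is.numeric(delta), length(r_standard) == 1L, r_standard > 0)
  if (any(delta <= -1000, na.rm = TRUE)) {
    stop("`delta` must exceed -1000 per mil (isotope ratio would be non-positive)")
  }
  r <- r_standard * (1 + delta / 1000)
  100 * r / (1 + r)
}

#' Convert atom percent 15N to delta-15N
#'
#' Exact inverse of [delta_to_atom_percent()].
#'
#' @param at_pct atom percent 15N, strictly inside (0, 100).
#' @inheritParams delta_to_atom_percent
#' @return delta-15N in per mil vs the reference.
#' @examples
#' atom_percent_to_delta(0.3663)  # ~0 per mil
#' @export
atom_percent_to_delta <- function(at_pct, r_standard = R15_AIR) {
  stopifnot(is.numeric(at_pct), length(r_standard) == 1L, r_standard > 0)
  if (any(at_pct <= 0 | at_pct >= 100, na.rm = TRUE)) {
    stop("`at_pct` must lie strictly between 0 and 100")
  }
  r <- at_pct / (100 - at_pct)
  1000 * (r / r_standard - 1)
}

#' Atom percent excess above a background
#'
#' The enrichment of a sample above its unlabeled background,
#' `at_true - at_bg`. The result may be negative; validity screening is the
#' caller's concern (see [compute_rates()]).
#'
#' @param at_true measured (blank-corrected) atom percent 15N, in `[0, 100]`.
#' @param at_bg background atom percent 15N, in `[0, 100]`.
#' @return Atom percent excess (APE), same units.
#' @examples
#' atom_percent_excess(9.24, 0.37)
#' @export
atom_percent_excess <- function(at_true, at_bg) {
  check_atpct(at_true, "at_true")
  check_atpct(at_bg, "at_bg")
  at_true - at_bg
}

#' Natural-abundance atom percent 15N
#'
#' Atom percent corresponding to delta = 0 vs the reference, i.e. the 15N
#' content of unlabeled material (~0.3663 at% vs AIR, 0.37 at 2 d.p.).
#'
#' @inheritParams delta_to_atom_percent
#' @return Atom percent 15N at natural abundance.
#' @export
natural_abundance_atpct <- function(r_standard = R15_AIR) {
  delta_to_atom_percent(0, r_standard)
}

check_atpct <- function(x, name) {
  if (any(x < 0 | x > 100, na.rm = TRUE)) {
    stop(sprintf("`%s` must lie in [0, 100] atom percent", name))
  }
  invisible(x)
}
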