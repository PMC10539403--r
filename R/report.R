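#' Render scenario outcomes as a publication-style table
#'
#' Formats a set of evaluated scenario outcomes the way the study's
#' scenario table is laid out: allocated areas with their percentage of
#' the suitable maxima, food potential with its percent-of-maximum
#' (A), net mitigation with its percent-of-maximum (B), and the
#' combined potential A + B. Percentages are rounded half-away-from-
#' zero to integers for display; the raw floats stay in the outcome
#' data.frame written alongside.
#'
#' @param outcomes data.frame of [evaluate_allocation()] rows.
#' @param area_recult_max,area_reforest_max suitable-area maxima (Mha)
#'   for the area percentages; defaults to the largest allocated area
#'   in `outcomes`.
#' @return data.frame of formatted strings, one row per scenario.
#' @export
render_scenario_table <- function(outcomes,
                                  area_recult_max = max(outcomes$area_recult),
                                  area_reforest_max =
                                    max(outcomes$area_reforest)) {
  pct <- function(x) sprintf("%d%%", as.integer(round_half_away(x)))
  area_pct <- function(a, mx) {
    sprintf("%.3g (%s)", a, if (mx > 0) pct(100 * a / mx) else "-")
  }
  data.frame(
    scenario = outcomes$scenario,
    recultivation_mha = mapply(area_pct, outcomes$area_recult,
                               area_recult_max),
    reforestation_mha = mapply(area_pct, outcomes$area_reforest,
                               area_reforest_max),
    food_pcal = sprintf("%.3g (%s)", outcomes$F, pct(outcomes$A)),
    mitigation_mtco2 = sprintf("%.3g (%s)", outcomes$C_net,
                               pct(outcomes$B)),
    combined = pct(outcomes$combined),
    stringsAsFactors = FALSE
  )
}

#' Render a prioritization sweep comparison table
#'
#' @param benefit output of [prioritization_benefit()].
#' @return data.frame of formatted strings.
#' @export
render_sweep_table <- function(benefit) {
  data.frame(
    fraction = sprintf("%d%%", as.integer(round_half_away(
      100 * benefit$fraction))),
    food_uplift = sprintf("%+.0f%%", round_half_away(benefit$uplift_F_pct)),
    mitigation_uplift = sprintf("%+.0f%%",
                                round_half_away(benefit$uplift_C_pct)),
    area_saved_mha = ifelse(is.na(benefit$area_saved_mha), "-",
                            sprintf("%.2f", benefit$area_saved_mha)),
    stringsAsFactors = FALSE
  )
}
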