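#' Integrated consumer-level calorie productivity
#'
#' Harvest-share-weighted mean of the per-crop calorie yields,
#' discounted to the consumer level by the local food-loss fraction and
#' the uniform food-waste fraction:
#'
#' `productivity_i = sum_j yield_j * share_ij * (1 - loss_i) * (1 - waste)`
#'
#' where the shares are each crop's fraction of the pixel's harvested
#' area. Pixels with no crop data (all shares zero) get productivity 0.
#'
#' @param stack an `env_stack`; per-pixel harvest shares must sum to 0
#'   or 1.
#' @return numeric vector, kcal yr^-1 ha^-1.
#' @export
integrated_productivity <- function(stack) {
  share <- stack$harvest_share
  if (is.null(dim(share))) share <- matrix(share, ncol = 1)
  rs <- rowSums(share)
  if (any(abs(rs) > 1e-8 & abs(rs - 1) > 1e-8)) {
    stop("harvest shares must sum to 0 or 1 per pixel", call. = FALSE)
  }
  as.numeric(share %*% stack$yield) *
    (1 - stack$food_loss) * (1 - stack$food_waste)
}

#' Food-production potential of a pixel selection
#'
#' @param selection logical vector over pixels (e.g. recultivated
#'   pixels of an allocation), or an `allocation` object whose
#'   `"recultivate"` pixels are used.
#' @param productivity per-pixel productivity (kcal yr^-1 ha^-1).
#' @param spec the shared [grid_spec()].
#' @return total in Pcal yr^-1 (1 Pcal = 1e12 kcal).
#' @export
food_potential <- function(selection, productivity, spec) {
  if (inherits(selection, "allocation")) {
    selection <- !is.na(selection$purpose) & selection$purpose == "recultivate"
  }
  sum(productivity[selection]) * spec$pixel_area / 1e12
}

#' One-time and amortized land-clearing emissions
#'
#' Recultivating an abandoned pixel clears the aboveground biomass
#' accumulated since abandonment; all of it is assumed immediately
#' oxidized. On pixels whose current (final-year) cover is a
#' regenerating class, accumulated carbon is the aboveground
#' accumulation rate times the years since abandonment; on all other
#' covers (grass, shrub, bareland) it is the standing biomass-carbon
#' stock. Carbon converts to CO2 with the stoichiometric factor 44/12,
#' and the amortized rate divides the one-time emission by the
#' accounting horizon.
#'
#' @param stack an `env_stack` (`agb_rate` in MgC yr^-1 ha^-1,
#'   `biomass_stock` in MgC ha^-1).
#' @param landcover_final integer class codes of the final year.
#' @param abandon_year per-pixel abandonment year (`NA` off abandoned
#'   pixels).
#' @param codebook class codebook naming the regenerating class
#'   (`forest_regrowth`).
#' @param horizon accounting horizon in years (default 30).
#' @param final_year calendar year of `landcover_final`.
#' @return list with `clear_emit` (MgCO2 ha^-1) and `clear_emit_rate`
#'   (MgCO2 yr^-1 ha^-1), `NA` where `abandon_year` is `NA`.
#' @export
clearing_emission <- function(stack, landcover_final, abandon_year,
                              codebook = default_codebook(),
                              horizon = 30,
                              final_year = stack$spec$year_end) {
  yrs <- final_year - abandon_year
  if (any(yrs < 0, na.rm = TRUE)) {
    stop("negative years since abandonment", call. = FALSE)
  }
  regen_codes <- codebook$code[codebook$class == "forest_regrowth"]
  regen <- landcover_final %in% regen_codes
  carbon <- ifelse(regen, stack$agb_rate * yrs, stack$biomass_stock)
  carbon[is.na(abandon_year)] <- NA_real_
  emit <- carbon * 44 / 12
  list(clear_emit = emit, clear_emit_rate = emit / horizon)
}

#' Assemble the per-pixel potential surfaces
#'
#' Bundles productivity, sequestration and clearing-emission grids into
#' one object consumed by the allocation scenarios.
#'
#' @param stack an `env_stack`.
#' @param series the (filtered) `landcover_series`, for the final-year
#'   cover.
#' @param map an `abandonment_map`.
#' @param horizon clearing amortization horizon (years).
#' @return object of class `potential_surfaces`: `productivity`,
#'   `seq` (total MgCO2 yr^-1 ha^-1), `clear_emit`, `clear_emit_rate`,
#'   `horizon`, `spec`.
#' @export
potential_surfaces <- function(stack, series, map, horizon = 30) {
  prod <- integrated_productivity(stack)
  final <- series$classes[, ncol(series$classes)]
  ce <- clearing_emission(stack, final, map$abandon_year,
                          codebook = series$codebook, horizon = horizon)
  structure(list(productivity = prod, seq = stack$seq_rate,
                 clear_emit = ce$clear_emit,
                 clear_emit_rate = ce$clear_emit_rate,
                 horizon = horizon, spec = map$spec),
            class = "potential_surfaces")
}

#' Net climate-change-mitigation potential of an allocation
#'
#' Sequestration credit on reforested pixels minus the amortized
#' clearing-emission debit on recultivated pixels. May be negative.
#'
#' @param allocation an `allocation` (see [representative_scenario()]),
#'   or a list with logical `reforest` and `recultivate` vectors.
#' @param surfaces a `potential_surfaces`.
#' @param spec the shared [grid_spec()].
#' @return total in MtCO2 yr^-1.
#' @export
net_mitigation <- function(allocation, surfaces, spec = surfaces$spec) {
  if (inherits(allocation, "allocation")) {
    ref <- !is.na(allocation$purpose) & allocation$purpose == "reforest"
    rec <- !is.na(allocation$purpose) & allocation$purpose == "recultivate"
  } else {
    ref <- allocation$reforest
    rec <- allocation$recultivate
  }
  credit <- sum(surfaces$seq[ref])
  debit <- sum(surfaces$clear_emit_rate[rec])
  (credit - debit) * spec$pixel_area / 1e6
}

#' Improvement levers for the achievable potentials
#'
#' Parameterized multipliers representing documented approaches to
#' raise the potentials: irrigated instead of rain-fed yields, closing
#' the yield gap toward attainable yields, halving (or otherwise
#' scaling) food waste and loss, and active reforestation outside
#' protected areas instead of pure natural regrowth.
#'
#' @param irrigation_multiplier factor (>= 1) on actual yields.
#' @param yield_gap_closure fraction in `[0, 1]` of the way from the
#'   (irrigation-adjusted) yield toward the attainable yield.
#' @param waste_loss_scaling factor applied to both the food-loss
#'   fractions and the food-waste scalar (0.5 = halving).
#' @param active_reforestation_multiplier factor (>= 1) on the
#'   sequestration rate outside protected areas (default 1 = natural
#'   regrowth everywhere; the study's nonspatial estimate for active
#'   reforestation is a 53% increase, i.e. 1.53).
#' @return object of class `lever_set`.
#' @export
lever_set <- function(irrigation_multiplier = 1,
                      yield_gap_closure = 0,
                      waste_loss_scaling = 1,
                      active_reforestation_multiplier = 1) {
  stopifnot(irrigation_multiplier >= 1,
            yield_gap_closure >= 0, yield_gap_closure <= 1,
            waste_loss_scaling >= 0,
            active_reforestation_multiplier >= 1)
  structure(list(irrigation_multiplier = irrigation_multiplier,
                 yield_gap_closure = yield_gap_closure,
                 waste_loss_scaling = waste_loss_scaling,
                 active_reforestation_multiplier =
                   active_reforestation_multiplier),
            class = "lever_set")
}

#' Apply improvement levers to the potential surfaces
#'
#' Productivity is recomputed from the stack with yields scaled by the
#' irrigation multiplier and moved `yield_gap_closure` of the way
#' toward the attainable yields (never downward), and with loss/waste
#' fractions scaled; the sequestration rate is scaled by the
#' active-reforestation multiplier outside protected areas only.
#' Clearing emissions are unchanged.
#'
#' @param surfaces a `potential_surfaces`.
#' @param stack the `env_stack` the surfaces were built from.
#' @param levers a [lever_set()].
#' @return a new `potential_surfaces`.
#' @export
apply_levers <- function(surfaces, stack, levers) {
  stopifnot(inherits(levers, "lever_set"))
  y <- stack$yield * levers$irrigation_multiplier
  y <- y + levers$yield_gap_closure * pmax(stack$attainable_yield - y, 0)
  loss <- stack$food_loss * levers$waste_loss_scaling
  waste <- stack$food_waste * levers$waste_loss_scaling
  share <- stack$harvest_share
  if (is.null(dim(share))) share <- matrix(share, ncol = 1)
  surfaces$productivity <- as.numeric(share %*% y) * (1 - loss) * (1 - waste)
  mult <- ifelse(stack$protected, 1, levers$active_reforestation_multiplier)
  surfaces$seq <- surfaces$seq * mult
  surfaces
}
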