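#' Landscape maxima for normalizing scenario outcomes
#'
#' `F_max` is the food potential with every recultivation-suitable
#' pixel recultivated; `C_max` is the gross sequestration with every
#' reforestation-suitable pixel reforested and no clearing debit.
#' Because the clearing debit is excluded from `C_max`, even the
#' climate-maximizing scenario can fall short of 100% when it
#' recultivates the recultivation-only pixels.
#'
#' @param types a `suitability_types`.
#' @param surfaces a `potential_surfaces`.
#' @param spec the shared [grid_spec()].
#' @return list with `F_max` (Pcal yr^-1) and `C_max` (MtCO2 yr^-1).
#' @export
landscape_maxima <- function(types, surfaces, spec = surfaces$spec) {
  list(
    F_max = food_potential(types$recult_suitable, surfaces$productivity, spec),
    C_max = sum(surfaces$seq[types$reforest_suitable]) * spec$pixel_area / 1e6
  )
}

# comparative-advantage margin of recultivating vs reforesting a pixel,
# on the additive A+B scale (pixel areas are uniform and cancel)
advantage_margin <- function(types, surfaces) {
  f_tot <- sum(surfaces$productivity[types$recult_suitable])
  c_tot <- sum(surfaces$seq[types$reforest_suitable])
  if (f_tot <= 0 || c_tot <= 0) {
    stop("degenerate landscape: one of the maxima is zero", call. = FALSE)
  }
  surfaces$productivity / f_tot -
    (surfaces$seq + surfaces$clear_emit_rate) / c_tot
}

new_allocation <- function(purpose, spec, scenario = NA_character_) {
  structure(list(purpose = purpose, spec = spec, scenario = scenario),
            class = "allocation")
}

#' @export
print.allocation <- function(x, ...) {
  cat(sprintf("<allocation> scenario: %s\n", x$scenario))
  print(table(x$purpose, useNA = "ifany"))
  invisible(x)
}

#' Allocate suitable abandoned land under a representative scenario
#'
#' Every suitable pixel is used (single-purpose pixels keep their only
#' purpose; `neither` pixels stay unused); the scenarios differ in how
#' the both-suitable pool is split:
#'
#' * `max_food`: every recultivation-suitable pixel is recultivated;
#'   the reforestation-only remainder is reforested.
#' * `max_climate`: every reforestation-suitable pixel is reforested;
#'   recultivation-only pixels are recultivated.
#' * `equal_allocation`: the pool is split so total recultivated area
#'   equals total reforested area (to within one pixel), assigning the
#'   pixels with the largest comparative advantage for recultivation
#'   first.
#' * `max_combined`: a both-suitable pixel is recultivated iff its
#'   normalized food contribution exceeds its normalized climate
#'   contribution (sequestration forgone plus clearing debit):
#'   `productivity_i / F_tot > (seq_i + clear_emit_rate_i) / C_tot`.
#'   For the additive combined objective A + B this pixelwise rule is
#'   exactly optimal among allocations that use all suitable land.
#'
#' @param name one of `"max_food"`, `"max_climate"`,
#'   `"equal_allocation"`, `"max_combined"`.
#' @param types a `suitability_types`.
#' @param surfaces a `potential_surfaces`.
#' @return an `allocation`: factor `purpose` over pixels with levels
#'   `recultivate`, `reforest`, `unused` (`NA` off abandoned pixels).
#' @export
representative_scenario <- function(name, types, surfaces) {
  name <- as.character(name)
  if (!name %in% c("max_food", "max_climate", "equal_allocation",
                   "max_combined")) {
    stop("unknown scenario name: ", name, call. = FALSE)
  }
  np <- length(types$type)
  purpose <- rep(NA_character_, np)
  abandoned <- !is.na(types$type)
  purpose[abandoned] <- "unused"
  recult_only <- which(types$type == "recult_only")
  reforest_only <- which(types$type == "reforest_only")
  both <- which(types$type == "both")
  purpose[recult_only] <- "recultivate"
  purpose[reforest_only] <- "reforest"

  if (length(both) > 0) {
    if (name == "max_food") {
      purpose[both] <- "recultivate"
    } else if (name == "max_climate") {
      purpose[both] <- "reforest"
    } else {
      adv <- advantage_margin(types, surfaces)
      if (name == "max_combined") {
        purpose[both] <- ifelse(adv[both] > 0, "recultivate", "reforest")
      } else {  # equal_allocation
        x <- (length(both) + length(reforest_only) - length(recult_only)) / 2
        x <- min(max(round(x), 0), length(both))
        ord <- both[order(-adv[both], both)]
        purpose[ord[seq_len(x)]] <- "recultivate"
        purpose[setdiff(both, ord[seq_len(x)])] <- "reforest"
      }
    }
  }

  new_allocation(factor(purpose, levels = c("recultivate", "reforest",
                                            "unused")),
                 types$spec, name)
}

#' Evaluate an allocation against the landscape maxima
#'
#' @param allocation an `allocation`.
#' @param surfaces a `potential_surfaces`.
#' @param F_max,C_max normalizing maxima (Pcal yr^-1, MtCO2 yr^-1);
#'   see [landscape_maxima()].
#' @param spec the shared [grid_spec()].
#' @return one-row data.frame (class `scenario_outcome`): `scenario`,
#'   `F` (Pcal yr^-1), `C_net` (MtCO2 yr^-1), `A`, `B`, `combined`
#'   (percent), `area_recult`, `area_reforest` (Mha).
#' @export
evaluate_allocation <- function(allocation, surfaces, F_max, C_max,
                                spec = surfaces$spec) {
  stopifnot(F_max > 0, C_max > 0)
  rec <- !is.na(allocation$purpose) & allocation$purpose == "recultivate"
  ref <- !is.na(allocation$purpose) & allocation$purpose == "reforest"
  f <- food_potential(rec, surfaces$productivity, spec)
  c_net <- net_mitigation(list(recultivate = rec, reforest = ref),
                          surfaces, spec)
  shares <- potential_shares(f, c_net, F_max, C_max)
  out <- data.frame(scenario = allocation$scenario,
                    F = f, C_net = c_net,
                    A = shares[["A"]], B = shares[["B"]],
                    combined = shares[["combined"]],
                    area_recult = sum(rec) * spec$pixel_area / 1e6,
                    area_reforest = sum(ref) * spec$pixel_area / 1e6,
                    stringsAsFactors = FALSE)
  class(out) <- c("scenario_outcome", class(out))
  out
}

#' Percent-of-maximum indicators and the combined potential
#'
#' `A = 100 F / F_max`, `B = 100 C_net / C_max`, and the combined
#' potential `A + B` — the additive indicator used to compare
#' scenarios.
#'
#' @param F achieved food potential; `F_max` its landscape maximum.
#' @param C_net achieved net mitigation; `C_max` its landscape maximum.
#' @return named vector `A`, `B`, `combined` (percent).
#' @examples
#' potential_shares(363, 290, 363, 1080)
#' @export
potential_shares <- function(F, C_net, F_max, C_max) {
  a <- 100 * F / F_max
  b <- 100 * C_net / C_max
  c(A = a, B = b, combined = a + b)
}

#' Fraction-constrained sweeps with and without prioritization
#'
#' For each fraction `f`, selects `round(f * n_abandoned)` pixels for
#' one purpose from that purpose's suitable pool — in descending order
#' of the purpose-relevant per-hectare rate (productivity for
#' recultivation, net sequestration for reforestation; ties broken by
#' row-major pixel index) when `strategy = "prioritized"`, or uniformly
#' at random when `strategy = "randomized"` — and evaluates the
#' outcome. Fractions are of the *total abandoned* area, so a large
#' fraction can exhaust the suitable pool; the whole pool is then used
#' and the shortfall flagged.
#'
#' @param types a `suitability_types`.
#' @param surfaces a `potential_surfaces`.
#' @param purpose `"recultivate"` or `"reforest"`.
#' @param fractions numeric vector in `(0, 1]`.
#' @param strategy `"prioritized"` or `"randomized"`.
#' @param seed seed for the randomized draws.
#' @param F_max,C_max normalizing maxima; computed from the landscape
#'   when omitted.
#' @param spec the shared [grid_spec()].
#' @return data.frame with one row per fraction: `fraction`,
#'   `strategy`, `purpose`, `n_selected`, `area_used` (Mha), `F`,
#'   `C_net`, `A`, `B`, `combined`, `shortfall`.
#' @export
fraction_sweep <- function(types, surfaces,
                           purpose = c("recultivate", "reforest"),
                           fractions = seq(0.1, 1, by = 0.1),
                           strategy = c("prioritized", "randomized"),
                           seed = 1L, F_max = NULL, C_max = NULL,
                           spec = surfaces$spec) {
  purpose <- match.arg(purpose)
  strategy <- match.arg(strategy)
  stopifnot(all(fractions > 0), all(fractions <= 1))
  if (is.null(F_max) || is.null(C_max)) {
    mx <- landscape_maxima(types, surfaces, spec)
    if (is.null(F_max)) F_max <- mx$F_max
    if (is.null(C_max)) C_max <- mx$C_max
  }
  abandoned <- !is.na(types$type)
  n_ab <- sum(abandoned)
  pool <- if (purpose == "recultivate") which(types$recult_suitable)
          else which(types$reforest_suitable)
  # reforesting incurs no clearing, so its net per-ha rate is the
  # gross regrowth sequestration rate
  rate <- if (purpose == "recultivate") surfaces$productivity else surfaces$seq
  ranked <- pool[order(-rate[pool], pool)]

  rows <- with_seed(seed, lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    n_target <- round(f * n_ab)
    shortfall <- n_target > length(pool)
    n_sel <- min(n_target, length(pool))
    sel <- if (strategy == "prioritized") ranked[seq_len(n_sel)]
           else resample(pool, n_sel)
    purp <- rep(NA_character_, length(types$type))
    purp[abandoned] <- "unused"
    purp[sel] <- purpose
    alloc <- new_allocation(factor(purp, levels = c("recultivate", "reforest",
                                                    "unused")),
                            spec, sprintf("%s_%s_f%.2f", purpose, strategy, f))
    ev <- evaluate_allocation(alloc, surfaces, F_max, C_max, spec)
    data.frame(fraction = f, strategy = strategy, purpose = purpose,
               n_selected = n_sel,
               area_used = n_sel * spec$pixel_area / 1e6,
               F = ev$F, C_net = ev$C_net, A = ev$A, B = ev$B,
               combined = ev$combined, shortfall = shortfall,
               stringsAsFactors = FALSE)
  }))
  do.call(rbind, rows)
}

#' Benefit of spatial prioritization
#'
#' Pairs a prioritized and a randomized sweep on the same fractions and
#' reports, per fraction, the percentage uplift of the prioritized
#' outcome for food and net mitigation, plus the extra area the
#' randomized strategy needs to match the prioritized output level
#' (linear interpolation along the randomized sweep; `NA` when the
#' level is not reached at any swept fraction).
#'
#' @param prioritized,randomized outputs of [fraction_sweep()] sharing
#'   `fractions` and `purpose`.
#' @return data.frame with `fraction`, `uplift_F_pct`, `uplift_C_pct`,
#'   `area_saved_mha`.
#' @export
prioritization_benefit <- function(prioritized, randomized) {
  if (!isTRUE(all.equal(prioritized$fraction, randomized$fraction)) ||
      !identical(prioritized$purpose[1], randomized$purpose[1])) {
    stop("sweeps must share fractions and purpose", call. = FALSE)
  }
  pct <- function(a, b) ifelse(b == 0, ifelse(a == 0, 0, NA), 100 * (a - b) / b)
  metric <- if (prioritized$purpose[1] == "recultivate") "F" else "C_net"
  lvl <- prioritized[[metric]]
  area_needed <- if (all(diff(randomized[[metric]]) == 0)) {
    rep(NA_real_, length(lvl))
  } else {
    stats::approx(randomized[[metric]], randomized$area_used, xout = lvl,
                  ties = "ordered", rule = 1)$y
  }
  data.frame(fraction = prioritized$fraction,
             uplift_F_pct = pct(prioritized$F, randomized$F),
             uplift_C_pct = pct(prioritized$C_net, randomized$C_net),
             area_saved_mha = area_needed - prioritized$area_used)
}
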