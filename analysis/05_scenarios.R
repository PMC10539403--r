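#!/usr/bin/env Rscript
# Stage 5 — allocation scenarios, trade-offs and prioritization.
#
# Evaluates the four representative allocations (maximize food,
# maximize climate mitigation, equal allocation, maximize combined
# potential), then sweeps the fraction of abandoned land used with and
# without spatial prioritization and quantifies the prioritization
# benefit.

source(file.path("analysis", "00_common.R"))

series <- read_landcover_series(INPUTS)
stack <- read_env_stack(INPUTS)
params <- abandonment_params()
filtered <- temporal_filter(series, params$filter_window)
map <- detect_abandonment(filtered, params)
presence <- detect_recultivation_presence(filtered, params)
model <- fit_recultivation_suitability(presence, stack, seed = SEED)
types <- classify_suitability(predict(model, stack, tau = 0.5), stack, map)
surfaces <- potential_surfaces(stack, series, map, horizon = 30)
mx <- landscape_maxima(types, surfaces)

outcomes <- do.call(rbind, lapply(
  c("max_food", "max_climate", "equal_allocation", "max_combined"),
  function(nm) {
    alloc <- representative_scenario(nm, types, surfaces)
    write_grid_asc(as.integer(alloc$purpose), series$spec,
                   file.path(RES, paste0("allocation_", nm, ".asc")))
    evaluate_allocation(alloc, surfaces, mx$F_max, mx$C_max)
  }))
save_csv(outcomes, "scenario_outcomes.csv")
save_csv(render_scenario_table(outcomes), "scenario_table.csv")
message("representative scenarios (A = % of max food, B = % of max climate):")
print(render_scenario_table(outcomes))

fr <- seq(0.1, 1, by = 0.1)
pri <- fraction_sweep(types, surfaces, "recultivate", fr, "prioritized",
                      F_max = mx$F_max, C_max = mx$C_max)
rnd <- fraction_sweep(types, surfaces, "recultivate", fr, "randomized",
                      seed = SEED, F_max = mx$F_max, C_max = mx$C_max)
ben_f <- prioritization_benefit(pri, rnd)
pri_c <- fraction_sweep(types, surfaces, "reforest", fr, "prioritized",
                        F_max = mx$F_max, C_max = mx$C_max)
rnd_c <- fraction_sweep(types, surfaces, "reforest", fr, "randomized",
                        seed = SEED, F_max = mx$F_max, C_max = mx$C_max)
ben_c <- prioritization_benefit(pri_c, rnd_c)

save_csv(rbind(pri, rnd, pri_c, rnd_c), "sweeps.csv")
save_csv(cbind(purpose = "recultivate", ben_f), "benefit_food.csv")
save_csv(cbind(purpose = "reforest", ben_c), "benefit_climate.csv")

at30 <- which(abs(fr - 0.3) < 1e-9)
message(sprintf(paste0("prioritization uplift at 30%% of abandoned land: ",
                       "food %+.0f%%, mitigation %+.0f%%"),
                ben_f$uplift_F_pct[at30], ben_c$uplift_C_pct[at30]))
message(sprintf("largest uplifts across fractions: food %+.0f%%, mitigation %+.0f%%",
                max(ben_f$uplift_F_pct), max(ben_c$uplift_C_pct)))
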