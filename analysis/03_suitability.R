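#!/usr/bin/env Rscript
# Stage 3 — suitability for recultivation and reforestation.
#
# Trains the presence-background recultivation model on historically
# recultivated pixels, predicts recultivatability with the
# default-prevalence calibration, applies the 0.2 cut and the
# protected-area mask, overlays the forest/woodland potential natural
# vegetation, and reports the four-way suitability typology.

source(file.path("analysis", "00_common.R"))

series <- read_landcover_series(INPUTS)
stack <- read_env_stack(INPUTS)
params <- abandonment_params()
filtered <- temporal_filter(series, params$filter_window)
map <- detect_abandonment(filtered, params)

presence <- detect_recultivation_presence(filtered, params)
message("training presences (historically recultivated pixels): ",
        sum(presence))
model <- fit_recultivation_suitability(presence, stack, seed = SEED)
print(model)

rcv <- predict(model, stack, tau = 0.5)
types <- classify_suitability(rcv, stack, map, threshold = 0.2)

write_grid_asc(rcv, series$spec, file.path(RES, "recultivability.asc"))
write_grid_asc(as.integer(types$type), series$spec,
               file.path(RES, "suitability_type.asc"))
save_csv(data.frame(term = names(model$coefficients),
                    estimate = model$coefficients),
         "suitability_coefficients.csv")

tab <- table(types$type)
shares <- 100 * tab / sum(tab)
save_csv(data.frame(type = names(tab), pixels = as.integer(tab),
                    share_pct = as.numeric(shares)),
         "suitability_typology.csv")
message("typology shares of abandoned land (%):")
print(round(shares, 1))
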