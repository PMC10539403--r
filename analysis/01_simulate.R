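#!/usr/bin/env Rscript
# Stage 1 — simulate the study landscape.
#
# Draws the annual land-cover series (with abandonment, recultivation
# and conversion events plus single-year classification noise) and the
# co-registered environment stack (crop yields and harvest shares,
# loss/waste fractions, sequestration rates, biomass stocks, potential
# natural vegetation, protected areas, suitability covariates), and
# writes everything as ASCII grids + CSV under results/analysis/inputs.

source(file.path("analysis", "00_common.R"))

spec <- study_spec()
sim <- do.call(simulate_study, c(list(spec = spec), LANDCOVER))

write_landcover_series(sim$series, INPUTS)
write_env_stack(sim$stack, INPUTS)

message("landscape: ", n_pixels(spec), " pixels, years ",
        spec$year_start, "-", spec$year_end)
print(table(sim$series$truth$status))
message(sprintf("mean sequestration rate %.1f MgCO2/yr/ha; food waste %.2f",
                mean(sim$stack$seq_rate), sim$stack$food_waste))
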