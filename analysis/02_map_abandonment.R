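#!/usr/bin/env Rscript
# Stage 2 — map abandoned cropland.
#
# Applies the 5-year moving-window temporal filter, then the decision
# rules: historically stable cropland (cropland throughout 1992-1997),
# a non-cropland run of at least five years persisting to 2020,
# exclusion of settlement/wetland conversions and of recultivated
# pixels. Writes the status grid and an area summary, and reports how
# well detection recovers the injected events despite the noise.

source(file.path("analysis", "00_common.R"))

series <- read_landcover_series(INPUTS)
params <- abandonment_params()
filtered <- temporal_filter(series, params$filter_window)
map <- detect_abandonment(filtered, params)

write_grid_asc(as.integer(map$status), series$spec,
               file.path(RES, "status.asc"))
write_grid_asc(map$abandon_year, series$spec,
               file.path(RES, "abandon_year.asc"))
save_csv(abandonment_summary(map), "abandonment_summary.csv")

print(abandonment_summary(map))
message(sprintf("abandonment rate: %.4f Mha/yr over %d years",
                abandonment_rate(map),
                series$spec$year_end - series$spec$year_start))

truth_ab <- series$truth$status == "abandoned"
got_ab <- map$status == "abandoned"
tp <- sum(truth_ab & got_ab)
message(sprintf("event recovery under noise: UA %.3f, PA %.3f",
                tp / sum(got_ab), tp / sum(truth_ab)))
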