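#!/usr/bin/env Rscript
# Stage 6 — stratified accuracy assessment and error-adjusted area.
#
# Draws a disproportionate stratified validation sample from the
# abandonment map (equal counts per stratum), labels it with the
# generator's noise-free truth (standing in for visual
# interpretation), and reports the stratified accuracy metrics and the
# error-adjusted abandoned area with its 95% interval.

source(file.path("analysis", "00_common.R"))

series <- read_landcover_series(INPUTS)
params <- abandonment_params()
map <- detect_abandonment(temporal_filter(series, params$filter_window),
                          params)

mc <- binary_map_class(map)
n_per <- min(400L, min(table(mc)))
samples <- stratified_sample(mc, n_per, seed = SEED)
samples$reference_class <- factor(
  ifelse(series$truth$status[samples$pixel] == "abandoned",
         "abandoned", "not_abandoned"),
  levels = levels(mc))

w <- strata_weights(mc)
report <- confusion_metrics(samples, w)
print(report)

total_mha <- n_pixels(series$spec) * series$spec$pixel_area / 1e6
area <- error_adjusted_area(samples, w, total_area = total_mha)
print(area, digits = 4)

save_csv(samples, "validation_samples.csv")
save_csv(area, "area_estimates.csv")
save_csv(data.frame(metric = c("overall_accuracy", "users_accuracy",
                               "producers_accuracy", "f1"),
                    value = c(report$overall_accuracy, report$users_accuracy,
                              report$producers_accuracy, report$f1)),
         "accuracy_metrics.csv")

truth_mha <- sum(series$truth$status == "abandoned") *
  series$spec$pixel_area / 1e6
a <- area[area$class == "abandoned", ]
message(sprintf(paste0("true abandoned area %.4f Mha; mapped %.4f; ",
                       "error-adjusted %.4f +/- %.4f"),
                truth_mha, a$mapped_area, a$area, a$ci95))
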