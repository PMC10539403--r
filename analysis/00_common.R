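# Shared settings for the analysis drivers. Every script sources this
# file, reads the previous stage's outputs from `results/analysis/`,
# and writes its own there, so the chain can be rerun stage by stage:
#
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_map_abandonment.R
#   ...
#
# The study landscape is a 120 x 120 grid (14,400 pixels of 9 ha) over
# 1992-2020 — large enough that every stage has a well-populated input
# (including the rare recultivated class that trains the suitability
# model) while the whole chain reruns in well under a minute.

library(fallowland)

RES <- file.path("results", "analysis")
INPUTS <- file.path(RES, "inputs")
SEED <- 20L

study_spec <- function() grid_spec(120, 120, seed = SEED)

# recultivation is denser here than the global historical rate so the
# suitability stage trains on a few hundred presences at this extent;
# the noise rate sits at the high end of single-year misclassification
# so the accuracy stage has real omission/commission errors to adjust
LANDCOVER <- list(p_abandon = 0.1, p_recult = 0.15, noise_rate = 0.05,
                  p_convert = 0.01)

dir.create(RES, recursive = TRUE, showWarnings = FALSE)

save_csv <- function(x, name) {
  utils::write.csv(x, file.path(RES, name), row.names = FALSE)
  message("wrote ", file.path(RES, name))
}
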