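# Fixture builders shared across test files. Everything is constructed
# in code; class codes come from the package's default codebook.

cb <- fallowland::default_codebook()
code_of <- function(name) cb$code[match(name, cb$class)]
CROP <- code_of("cropland_rainfed")
CROP2 <- code_of("cropland_irrigated")
GRASS <- code_of("grassland")
SHRUB <- code_of("shrubland")
FOREST <- code_of("forest_regrowth")
BARE <- code_of("bareland")
BUILT <- code_of("built_up")
WETLAND <- code_of("wetland")

# landcover_series from an explicit pixels x years class matrix
make_series <- function(cls, spec = NULL, years = NULL,
                        codebook = cb, truth = NULL) {
  cls <- matrix(as.integer(cls), nrow = NROW(cls))
  if (is.null(spec)) {
    spec <- fallowland::grid_spec(nrow(cls), 1,
                                  year_start = 1992,
                                  year_end = 1992 + ncol(cls) - 1)
  }
  if (is.null(years)) years <- fallowland::grid_years(spec)
  structure(list(classes = cls, years = years, codebook = codebook,
                 spec = spec, truth = truth),
            class = "landcover_series")
}

# a per-pixel trajectory: cropland up to (from - 1), `dest` from `from`
# to `until`, cropland again afterwards
trajectory <- function(years, from, dest, until = max(years),
                       crop = CROP) {
  ifelse(years < from | years > until, crop, dest)
}

# minimal suitability_types over a vector of type labels (NA = not
# abandoned)
make_types <- function(type, spec) {
  type <- factor(type, levels = c("recult_only", "reforest_only", "both",
                                  "neither"))
  structure(list(
    recultivability = rep(NA_real_, length(type)),
    type = type,
    recult_suitable = !is.na(type) & type %in% c("recult_only", "both"),
    reforest_suitable = !is.na(type) & type %in% c("reforest_only", "both"),
    threshold = 0.2, spec = spec
  ), class = "suitability_types")
}

# minimal potential_surfaces from explicit per-ha rates
make_surfaces <- function(productivity, seq, clear_emit_rate, spec,
                          horizon = 30) {
  structure(list(productivity = productivity, seq = seq,
                 clear_emit = clear_emit_rate * horizon,
                 clear_emit_rate = clear_emit_rate,
                 horizon = horizon, spec = spec),
            class = "potential_surfaces")
}

# minimal env_stack for the potentials/suitability units
make_stack <- function(spec, yield, harvest_share, food_loss = 0,
                       food_waste = 0, seq_rate = NULL, agb_rate = NULL,
                       biomass_stock = NULL, pnv_class = NULL,
                       protected = NULL, covariates = NULL,
                       attainable_yield = NULL) {
  np <- fallowland::n_pixels(spec)
  if (is.null(dim(harvest_share))) {
    harvest_share <- matrix(harvest_share, nrow = np)
  }
  structure(list(
    yield = yield,
    attainable_yield = if (is.null(attainable_yield)) yield * 1.4
                       else attainable_yield,
    harvest_share = harvest_share,
    food_loss = rep_len(food_loss, np),
    food_waste = food_waste,
    seq_rate = if (is.null(seq_rate)) rep(0, np) else rep_len(seq_rate, np),
    agb_rate = if (is.null(agb_rate)) rep(0, np) else rep_len(agb_rate, np),
    biomass_stock = if (is.null(biomass_stock)) rep(0, np)
                    else rep_len(biomass_stock, np),
    pnv_class = if (is.null(pnv_class)) rep(1L, np)
                else rep_len(pnv_class, np),
    pnv_forest_codes = c(1L, 2L),
    protected = if (is.null(protected)) rep(FALSE, np)
                else rep_len(protected, np),
    covariates = covariates,
    recult_propensity = NULL,
    spec = spec, config = NULL
  ), class = "env_stack")
}

# abandonment_map with a given status vector
make_map <- function(status, spec, abandon_year = NULL) {
  status <- factor(status, levels = c("never_cropland", "stable_cropland",
                                      "abandoned", "recultivated_excluded",
                                      "converted_excluded"))
  structure(list(status = status,
                 abandon_year = if (is.null(abandon_year)) {
                   ifelse(status == "abandoned", 2010L, NA_integer_)
                 } else abandon_year,
                 fallow_run_length = rep(NA_integer_, length(status)),
                 params = fallowland::abandonment_params(),
                 spec = spec),
            class = "abandonment_map")
}

# independent brute-force windowed-mode oracle for the temporal filter:
# plain loops, shared logic with nothing in the package
oracle_filter <- function(x, window) {
  half <- (window - 1) %/% 2
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    idx <- pmin(pmax((i - half):(i + half), 1), n)
    win <- x[idx]
    tab <- table(win)
    mx <- max(tab)
    if (mx >= half + 1) {
      mode_val <- as.integer(names(tab)[which.max(tab)])
      if (mode_val != x[i]) out[i] <- mode_val
    }
  }
  out
}

# map generator truth labels onto detector status labels
truth_as_status <- function(truth) {
  ifelse(truth$status == "recultivated", "recultivated_excluded",
         truth$status)
}
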