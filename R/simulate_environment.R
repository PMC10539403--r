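#' Configure the synthetic environment surfaces
#'
#' Defaults emulate the statistical structure of the study-scale
#' inputs: 15 food crops with calorie yields spanning roughly
#' 2-12 x 10^6 kcal yr^-1 ha^-1 (so the harvest-share-weighted
#' productivity lands near the ~6 x 10^6 implied by 363 Pcal yr^-1 over
#' 61 Mha), a total (above+belowground) sequestration-rate surface with
#' mean 11.5 MgCO2 yr^-1 ha^-1 (the reported global average on suitable
#' abandoned cropland), a uniform food-waste fraction of 0.17, and
#' productivity/sequestration gradients pointing in opposite directions
#' so that spatial prioritization matters.
#'
#' @param n_crops number of crops J (>= 1).
#' @param yield_range range (kcal yr^-1 ha^-1) across which crop
#'   calorie yields are evenly spread.
#' @param attainable_factor attainable yield as a multiple of actual
#'   yield (the yield-gap ceiling used by the levers).
#' @param productivity_gradient,seq_gradient gradient strengths in
#'   `[-1, 1]` for the latent productivity field and the sequestration
#'   field; opposite signs give opposing spatial trends.
#' @param sigma smoothing kernel sd in pixels for all autocorrelated
#'   fields.
#' @param seq_mean,seq_sd mean and spatial sd of the sequestration rate
#'   (MgCO2 yr^-1 ha^-1); `seq_sd = 0` gives a constant surface.
#' @param agb_fraction fraction of the sequestration rate attributable
#'   to aboveground biomass (the rest is the root compartment inferred
#'   from root-to-shoot ratios).
#' @param stock_mean,stock_sd aboveground biomass-carbon stock surface
#'   (MgC ha^-1) used for non-regenerating cover.
#' @param loss_range range of the per-pixel food-loss fraction.
#' @param food_waste scalar consumer food-waste fraction.
#' @param pnv_forest_frac fraction of the landscape whose potential
#'   natural vegetation is forest or woodland.
#' @param protected_frac fraction of the landscape inside protected
#'   areas (contiguous blobs); the default matches the ~18% of
#'   reforestation-suitable abandoned land reported inside protected
#'   areas at the global scale.
#' @param n_covariates number of recultivation-driver covariates.
#' @param covariate_cor correlation (vector or scalar, each in
#'   (-1, 1)) between each covariate and the latent recultivation
#'   propensity.
#' @param no_crop_frac fraction of pixels with no crop data (harvest
#'   shares summing to 0).
#' @return a plain list of configuration values for
#'   [generate_environment()].
#' @export
environment_config <- function(n_crops = 15,
                               yield_range = c(2e6, 1.2e7),
                               attainable_factor = 1.4,
                               productivity_gradient = 0.7,
                               seq_gradient = -0.7,
                               sigma = 3,
                               seq_mean = 11.5, seq_sd = 4,
                               agb_fraction = 0.76,
                               stock_mean = 10, stock_sd = 5,
                               loss_range = c(0.02, 0.30),
                               food_waste = 0.17,
                               pnv_forest_frac = 0.8,
                               protected_frac = 0.18,
                               n_covariates = 5,
                               covariate_cor = 0.6,
                               no_crop_frac = 0.03) {
  stopifnot(n_crops >= 1, all(abs(covariate_cor) < 1),
            food_waste >= 0, food_waste < 1, seq_sd >= 0)
  as.list(environment())
}

#' Generate the co-registered environment stack
#'
#' Builds every non-land-cover input layer on the shared grid: per-crop
#' calorie yields and per-pixel harvest shares, food-loss fractions and
#' the food-waste scalar, total and aboveground-only carbon
#' sequestration rates, standing biomass-carbon stocks, a potential-
#' natural-vegetation class grid, a protected-area mask, and
#' suitability covariates correlated with a latent recultivation
#' propensity. Productivity and sequestration surfaces are spatially
#' autocorrelated with opposing gradients (configurable), so that
#' ranking pixels by one rate tends to pick the low end of the other
#' and prioritization scenarios have real trade-offs.
#'
#' @param spec a [grid_spec()]; the RNG is seeded from
#'   `spec$seed + 1` so the land-cover draw and the environment draw
#'   are independent streams.
#' @param config see [environment_config()].
#' @return object of class `env_stack`: list with `yield` (J),
#'   `attainable_yield` (J), `harvest_share` (pixels x J, rows summing
#'   to 0 or 1), `food_loss`, `food_waste`, `seq_rate`, `agb_rate`,
#'   `biomass_stock`, `pnv_class` (1 forest, 2 woodland, 3 grassland,
#'   4 other; forest codes in `pnv_forest_codes`), `protected`,
#'   `covariates` (pixels x K), `recult_propensity` (latent,
#'   standardized), `spec`, `config`.
#' @export
generate_environment <- function(spec, config = environment_config()) {
  np <- n_pixels(spec)
  J <- config$n_crops
  K <- config$n_covariates
  rho <- rep_len(config$covariate_cor, K)
  stopifnot(all(abs(rho) < 1))

  with_seed(spec$seed + 1L, {
    # latent fertility/accessibility field drives productivity shares
    fert <- gaussian_field(spec, config$sigma, config$productivity_gradient)
    seqf <- gaussian_field(spec, config$sigma, config$seq_gradient)

    yield <- seq(config$yield_range[1], config$yield_range[2], length.out = J)
    # harvest shares: fertile pixels weight high-yield crops via a
    # softmax over crop loadings, plus per-pixel noise
    load <- seq(-1, 1, length.out = J)
    lin <- outer(fert, load) + matrix(stats::rnorm(np * J, sd = 0.5), np, J)
    share <- exp(lin)
    share <- share / rowSums(share)
    no_crop <- stats::runif(np) < config$no_crop_frac
    share[no_crop, ] <- 0

    loss <- config$loss_range[1] +
      (config$loss_range[2] - config$loss_range[1]) *
        stats::pnorm(gaussian_field(spec, config$sigma))

    seq_rate <- pmax(0, config$seq_mean + config$seq_sd * seqf)
    agb_rate <- seq_rate * (12 / 44) * config$agb_fraction  # MgC yr-1 ha-1
    stock <- pmax(0, config$stock_mean +
                    config$stock_sd * gaussian_field(spec, config$sigma))

    pnv_field <- gaussian_field(spec, config$sigma * 2)
    q <- stats::quantile(pnv_field, 1 - config$pnv_forest_frac)
    pnv <- ifelse(pnv_field >= q,
                  ifelse(pnv_field >= stats::quantile(pnv_field, 0.6), 1L, 2L),
                  ifelse(stats::runif(np) < 0.7, 3L, 4L))

    prot_field <- gaussian_field(spec, config$sigma * 2)
    prot <- prot_field >= stats::quantile(prot_field, 1 - config$protected_frac)

    # covariates: rho * latent + sqrt(1 - rho^2) * smooth noise, with the
    # noise orthogonalized against the latent field so the configured
    # correlation holds exactly in-sample (spatial autocorrelation would
    # otherwise inflate its sampling error)
    propensity <- standardize(gaussian_field(spec, config$sigma))
    covs <- vapply(seq_len(K), function(k) {
      z <- standardize(gaussian_field(spec, config$sigma))
      if (stats::sd(propensity) > 0) {
        z <- z - propensity * sum(z * propensity) / sum(propensity^2)
        z <- standardize(z)
      }
      rho[k] * propensity + sqrt(1 - rho[k]^2) * z
    }, numeric(np))

    structure(list(
      yield = yield,
      attainable_yield = yield * config$attainable_factor,
      harvest_share = share,
      food_loss = loss,
      food_waste = config$food_waste,
      seq_rate = seq_rate,
      agb_rate = agb_rate,
      biomass_stock = stock,
      pnv_class = pnv,
      pnv_forest_codes = c(1L, 2L),
      protected = prot,
      covariates = covs,
      recult_propensity = propensity,
      spec = spec,
      config = config
    ), class = "env_stack")
  })
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf(paste0("<env_stack> %d pixels, %d crops, %d covariates; ",
                     "mean seq rate %.1f MgCO2/yr/ha, waste %.2f\n"),
              length(x$food_loss), length(x$yield), ncol(x$covariates),
              mean(x$seq_rate), x$food_waste))
  invisible(x)
}

#' Simulate a complete synthetic study landscape
#'
#' Convenience wrapper that draws the environment stack first and then
#' the land-cover series, passing the environment's latent
#' recultivation propensity into the land-cover generator so that
#' recultivation events concentrate where the suitability covariates
#' say they should. All randomness derives from `spec$seed`.
#'
#' @param spec a [grid_spec()].
#' @param env_config see [environment_config()].
#' @param ... passed to [generate_landcover_series()].
#' @return list with `series` (a `landcover_series`) and `stack`
#'   (an `env_stack`).
#' @export
simulate_study <- function(spec, env_config = environment_config(), ...) {
  stack <- generate_environment(spec, env_config)
  series <- generate_landcover_series(
    spec, recult_propensity = stack$recult_propensity, ...
  )
  list(series = series, stack = stack)
}

#' Write and read an environment stack as ASCII grids plus CSV/YAML
#'
#' Continuous and class layers go to one `.asc` each (`harvest_share`
#' and `covariates` to one file per column), crop yields to
#' `yields.csv`, and scalars (`food_waste`, PNV forest codes) to
#' `stack.yml`.
#'
#' @param stack an `env_stack`.
#' @param dir output directory.
#' @return `write_env_stack()` returns `dir` invisibly;
#'   `read_env_stack()` rebuilds the `env_stack` (without `config`).
#' @export
write_env_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- stack$spec
  write_grid_asc(stack$food_loss, spec, file.path(dir, "food_loss.asc"))
  write_grid_asc(stack$seq_rate, spec, file.path(dir, "seq_rate.asc"))
  write_grid_asc(stack$agb_rate, spec, file.path(dir, "agb_rate.asc"))
  write_grid_asc(stack$biomass_stock, spec, file.path(dir, "biomass_stock.asc"))
  write_grid_asc(stack$pnv_class, spec, file.path(dir, "pnv_class.asc"))
  write_grid_asc(as.numeric(stack$protected), spec,
                 file.path(dir, "protected.asc"))
  for (j in seq_len(ncol(stack$harvest_share))) {
    write_grid_asc(stack$harvest_share[, j], spec,
                   file.path(dir, sprintf("harvest_share_%02d.asc", j)))
  }
  for (k in seq_len(ncol(stack$covariates))) {
    write_grid_asc(stack$covariates[, k], spec,
                   file.path(dir, sprintf("covariate_%02d.asc", k)))
  }
  utils::write.csv(data.frame(crop = seq_along(stack$yield),
                              yield = stack$yield,
                              attainable_yield = stack$attainable_yield),
                   file.path(dir, "yields.csv"), row.names = FALSE)
  yaml::write_yaml(c(stack$spec[c("n_rows", "n_cols", "pixel_area",
                                  "year_start", "year_end", "seed")],
                     list(food_waste = stack$food_waste,
                          pnv_forest_codes = stack$pnv_forest_codes,
                          n_crops = ncol(stack$harvest_share),
                          n_covariates = ncol(stack$covariates))),
                  file.path(dir, "stack.yml"))
  invisible(dir)
}

#' @rdname write_env_stack
#' @export
read_env_stack <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "stack.yml"))
  spec <- grid_spec(meta$n_rows, meta$n_cols, meta$pixel_area,
                    meta$year_start, meta$year_end, meta$seed)
  grid <- function(name) read_grid_asc(file.path(dir, name))$values
  yields <- utils::read.csv(file.path(dir, "yields.csv"))
  share <- vapply(seq_len(meta$n_crops), function(j) {
    grid(sprintf("harvest_share_%02d.asc", j))
  }, numeric(n_pixels(spec)))
  covs <- vapply(seq_len(meta$n_covariates), function(k) {
    grid(sprintf("covariate_%02d.asc", k))
  }, numeric(n_pixels(spec)))
  structure(list(
    yield = yields$yield,
    attainable_yield = yields$attainable_yield,
    harvest_share = share,
    food_loss = grid("food_loss.asc"),
    food_waste = meta$food_waste,
    seq_rate = grid("seq_rate.asc"),
    agb_rate = grid("agb_rate.asc"),
    biomass_stock = grid("biomass_stock.asc"),
    pnv_class = as.integer(grid("pnv_class.asc")),
    pnv_forest_codes = as.integer(unlist(meta$pnv_forest_codes)),
    protected = grid("protected.asc") > 0,
    covariates = covs,
    recult_propensity = NULL,
    spec = spec,
    config = NULL
  ), class = "env_stack")
}
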