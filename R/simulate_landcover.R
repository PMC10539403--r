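#' Default land-cover codebook
#'
#' Class codes loosely follow the ESA-CCI numbering. Two cropland codes
#' are included so that the aggregation of multiple cropland classes
#' into a single cropland layer is exercised; `is_cropland` flags them.
#'
#' @return data.frame with columns `code`, `class`, `is_cropland`.
#' @export
default_codebook <- function() {
  data.frame(
    code = c(10L, 20L, 50L, 120L, 130L, 180L, 190L, 200L, 210L),
    class = c("cropland_rainfed", "cropland_irrigated", "forest_regrowth",
              "shrubland", "grassland", "wetland", "built_up",
              "bareland", "water"),
    is_cropland = c(TRUE, TRUE, rep(FALSE, 7)),
    stringsAsFactors = FALSE
  )
}

codebook_codes <- function(codebook, classes) {
  codebook$code[match(classes, codebook$class)]
}

# sample() that never treats a length-1 vector as 1:n
resample <- function(x, ...) x[sample.int(length(x), ...)]

#' Simulate an annual land-cover class series with abandonment events
#'
#' Draws each pixel as one of: never-cropland (a constant natural
#' class), stable cropland, cropland abandoned at a year `t` (followed
#' by at least `min_fallow_years` of a non-cropland destination class
#' persisting to the end of the record), cropland abandoned and later
#' recultivated, or (optionally) cropland converted to an excluded
#' destination (built-up / wetland). Single-pixel-year misclassification
#' noise then flips pixel-years to a uniformly chosen other class.
#'
#' The generator returns its own ground-truth event table; with
#' `noise_rate = 0` the abandonment detector must recover it exactly,
#' which makes the generator the oracle for the mapping stage.
#'
#' @param spec a [grid_spec()]; the RNG is seeded from `spec$seed`.
#' @param p_abandon probability that a stable-cropland pixel is
#'   abandoned at some point. The study-scale analogue is the ~7% of
#'   active cropland identified as abandoned; the default emulates that
#'   rate.
#' @param p_recult probability that an abandoned pixel is later
#'   recultivated (the study's ~2.8 Mha recultivated against 101 Mha
#'   abandoned motivates the default).
#' @param noise_rate per-pixel-year probability of a misclassification
#'   flip.
#' @param frac_cropland fraction of the landscape that is cropland at
#'   the start (spatially clumped).
#' @param p_convert probability that a stable-cropland pixel is instead
#'   converted to an excluded destination class (built-up or wetland).
#' @param recult_propensity optional numeric vector (length
#'   `n_pixels(spec)`, standardized): pixels with higher values are more
#'   likely to be the recultivated ones, which couples recultivation
#'   presence to the suitability covariates built from the same latent
#'   field.
#' @param recult_coupling log-odds slope of the latent propensity in
#'   the recultivation draw; the default gives the suitability model a
#'   clear but imperfect signal (training AUC around 0.85, in the range
#'   reported for presence-background land-use models).
#' @param min_fallow_years minimum injected fallow-run length; must
#'   match the detector's rule for oracle recovery.
#' @param stable_years years during which event pixels are guaranteed
#'   cropland (the historically-stable-cropland window).
#' @param codebook class codebook; see [default_codebook()].
#' @return object of class `landcover_series`: list with `classes`
#'   (integer matrix, pixels x years), `years`, `codebook`, `spec`, and
#'   `truth` (data.frame: `pixel`, `status`, `abandon_year`,
#'   `fallow_run_length`, `recult_year`).
#' @export
generate_landcover_series <- function(spec,
                                      p_abandon = 0.08,
                                      p_recult = 0.03,
                                      noise_rate = 0.02,
                                      frac_cropland = 0.5,
                                      p_convert = 0,
                                      recult_propensity = NULL,
                                      recult_coupling = 3,
                                      min_fallow_years = 5,
                                      stable_years = 1992:1997,
                                      codebook = default_codebook()) {
  stopifnot(p_abandon >= 0, p_abandon <= 1, p_recult >= 0, p_recult <= 1,
            noise_rate >= 0, noise_rate <= 1, p_convert >= 0,
            p_abandon + p_convert <= 1)
  years <- grid_years(spec)
  ny <- length(years)
  np <- n_pixels(spec)
  if (!all(stable_years %in% years)) {
    stop("`stable_years` must lie inside the series years", call. = FALSE)
  }
  first_event_year <- max(stable_years) + 1L
  last_abandon_year <- spec$year_end - min_fallow_years + 1L
  if ((p_abandon > 0 || p_recult > 0) && first_event_year > last_abandon_year) {
    stop("impossible event layout: no year allows a ",
         min_fallow_years, "-year fallow run after the stable window",
         call. = FALSE)
  }

  crop_codes <- codebook$code[codebook$is_cropland]
  natural <- codebook_codes(codebook, c("forest_regrowth", "grassland",
                                        "shrubland", "bareland", "water"))
  # destination mix mirrors the study's final-cover breakdown of
  # reforestation-suitable abandoned land: regrowth 65%, grass 14%,
  # shrub 10%, bare 11%
  dest_codes <- codebook_codes(codebook, c("forest_regrowth", "grassland",
                                           "shrubland", "bareland"))
  dest_w <- c(0.65, 0.14, 0.10, 0.11)
  excl_codes <- codebook_codes(codebook, c("built_up", "wetland"))

  with_seed(spec$seed, {
    # clumped cropland extent
    crop_mask <- gaussian_field(spec, sigma = 4) <
      stats::qnorm(min(1, max(0, frac_cropland)))
    base_code <- ifelse(stats::runif(np) < 0.8, crop_codes[1],
                        crop_codes[min(2, length(crop_codes))])
    never_code <- sample(natural, np, replace = TRUE)

    cls <- matrix(0L, nrow = np, ncol = ny)
    status <- rep("never_cropland", np)
    abandon_year <- rep(NA_integer_, np)
    fallow_len <- rep(NA_integer_, np)
    recult_year <- rep(NA_integer_, np)

    cls[!crop_mask, ] <- never_code[!crop_mask]
    idx_crop <- which(crop_mask)
    cls[idx_crop, ] <- base_code[idx_crop]
    status[idx_crop] <- "stable_cropland"

    u <- stats::runif(length(idx_crop))
    ev_ab <- idx_crop[u < p_abandon]
    ev_cv <- idx_crop[u >= p_abandon & u < p_abandon + p_convert]

    if (length(ev_ab) > 0) {
      # recultivation preferentially hits high-propensity pixels
      p_r <- if (is.null(recult_propensity)) rep(p_recult, length(ev_ab)) else {
        stats::plogis(stats::qlogis(max(p_recult, 1e-12)) +
                        recult_coupling * recult_propensity[ev_ab])
      }
      if (p_recult == 0) p_r <- rep(0, length(ev_ab))
      is_rec <- stats::runif(length(ev_ab)) < p_r

      # abandoned-to-end pixels: t uniform over years leaving >= min_fallow
      ab_only <- ev_ab[!is_rec]
      if (length(ab_only) > 0) {
        t_ab <- resample(first_event_year:last_abandon_year, length(ab_only),
                         replace = TRUE)
        d_ab <- sample(dest_codes, length(ab_only), replace = TRUE, prob = dest_w)
        for (k in seq_along(ab_only)) {
          p <- ab_only[k]
          yi <- which(years >= t_ab[k])
          cls[p, yi] <- d_ab[k]
          status[p] <- "abandoned"
          abandon_year[p] <- t_ab[k]
          fallow_len[p] <- length(yi)
        }
      }

      # recultivated pixels: fallow run of >= min_fallow, then cropland again
      rec <- ev_ab[is_rec]
      if (length(rec) > 0) {
        last_rec_abandon <- spec$year_end - min_fallow_years
        if (first_event_year > last_rec_abandon) {
          stop("impossible event layout: recultivation needs a fallow run ",
               "plus at least one cropland year before the series end",
               call. = FALSE)
        }
        t_rc <- resample(first_event_year:last_rec_abandon, length(rec),
                         replace = TRUE)
        d_rc <- sample(dest_codes, length(rec), replace = TRUE, prob = dest_w)
        for (k in seq_along(rec)) {
          p <- rec[k]
          run_max <- spec$year_end - t_rc[k]          # leaves >= 1 crop year
          L <- resample(min_fallow_years:run_max, 1)
          yi <- which(years >= t_rc[k] & years < t_rc[k] + L)
          cls[p, yi] <- d_rc[k]
          status[p] <- "recultivated"
          abandon_year[p] <- t_rc[k]
          fallow_len[p] <- L
          recult_year[p] <- t_rc[k] + L
        }
      }
    }

    if (length(ev_cv) > 0) {
      t_cv <- resample(first_event_year:last_abandon_year, length(ev_cv),
                       replace = TRUE)
      d_cv <- sample(excl_codes, length(ev_cv), replace = TRUE)
      for (k in seq_along(ev_cv)) {
        p <- ev_cv[k]
        cls[p, which(years >= t_cv[k])] <- d_cv[k]
        status[p] <- "converted_excluded"
        abandon_year[p] <- t_cv[k]
      }
    }

    if (noise_rate > 0) {
      flips <- which(stats::runif(np * ny) < noise_rate)
      if (length(flips) > 0) {
        cur <- cls[flips]
        new <- sample(codebook$code, length(flips), replace = TRUE)
        same <- new == cur
        while (any(same)) {
          new[same] <- sample(codebook$code, sum(same), replace = TRUE)
          same <- new == cur
        }
        cls[flips] <- new
      }
    }

    truth <- data.frame(pixel = seq_len(np), status = status,
                        abandon_year = abandon_year,
                        fallow_run_length = fallow_len,
                        recult_year = recult_year,
                        stringsAsFactors = FALSE)
    structure(list(classes = cls, years = years, codebook = codebook,
                   spec = spec, truth = truth),
              class = "landcover_series")
  })
}

#' @export
print.landcover_series <- function(x, ...) {
  cat(sprintf("<landcover_series> %d pixels x %d years (%d-%d), %d classes\n",
              nrow(x$classes), ncol(x$classes), min(x$years), max(x$years),
              nrow(x$codebook)))
  print(table(x$truth$status))
  invisible(x)
}

#' Merge all cropland classes into one code
#'
#' All codebook entries flagged `is_cropland` are merged to a single
#' aggregate cropland code before any detection rule is applied, so the
#' detector sees one cropland class regardless of how many cropland
#' types the source product distinguishes. Non-cropland classes are
#' left distinct (the exclusion rules need the destination class).
#'
#' @param series a `landcover_series`.
#' @return the series with cropland codes replaced by the aggregate
#'   code `1` and the codebook updated accordingly.
#' @export
aggregate_cropland <- function(series) {
  crop_codes <- series$codebook$code[series$codebook$is_cropland]
  if (length(crop_codes) == 0) stop("codebook has no cropland class", call. = FALSE)
  if (identical(crop_codes, 1L)) return(series)
  cls <- series$classes
  cls[cls %in% crop_codes] <- 1L
  cb <- series$codebook[!series$codebook$is_cropland, , drop = FALSE]
  cb <- rbind(data.frame(code = 1L, class = "cropland", is_cropland = TRUE,
                         stringsAsFactors = FALSE), cb)
  series$classes <- cls
  series$codebook <- cb
  series
}

#' Write and read a land-cover series as per-year ASCII grids plus CSV
#'
#' One `.asc` grid per year (`lc_<year>.asc`), the codebook as
#' `codebook.csv`, and the ground-truth event table (when present) as
#' `events.csv`, all under `dir`. The grid seed is recorded in
#' `series.yml` alongside the grid dimensions.
#'
#' @param series a `landcover_series`.
#' @param dir output directory (created if missing).
#' @return `write_landcover_series()` returns `dir` invisibly;
#'   `read_landcover_series()` rebuilds the `landcover_series`.
#' @export
write_landcover_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(series$years)) {
    write_grid_asc(series$classes[, i], series$spec,
                   file.path(dir, sprintf("lc_%d.asc", series$years[i])))
  }
  utils::write.csv(series$codebook, file.path(dir, "codebook.csv"),
                   row.names = FALSE)
  if (!is.null(series$truth)) {
    utils::write.csv(series$truth, file.path(dir, "events.csv"),
                     row.names = FALSE)
  }
  yaml::write_yaml(series$spec[c("n_rows", "n_cols", "pixel_area",
                                 "year_start", "year_end", "seed")],
                   file.path(dir, "series.yml"))
  invisible(dir)
}

#' @rdname write_landcover_series
#' @export
read_landcover_series <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "series.yml"))
  spec <- grid_spec(meta$n_rows, meta$n_cols, meta$pixel_area,
                    meta$year_start, meta$year_end, meta$seed)
  years <- grid_years(spec)
  cls <- matrix(0L, n_pixels(spec), length(years))
  for (i in seq_along(years)) {
    g <- read_grid_asc(file.path(dir, sprintf("lc_%d.asc", years[i])))
    cls[, i] <- as.integer(g$values)
  }
  codebook <- utils::read.csv(file.path(dir, "codebook.csv"),
                              stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "events.csv")
  truth <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  }
  structure(list(classes = cls, years = years, codebook = codebook,
                 spec = spec, truth = truth),
            class = "landcover_series")
}
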