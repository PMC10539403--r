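#' Parameters of the abandonment decision rules
#'
#' @param min_fallow_years minimum consecutive non-cropland years for a
#'   pixel to count as abandoned (FAO definition: at least five).
#' @param stable_years the historically-stable-cropland window: a pixel
#'   is only eligible if it is cropland in every one of these years.
#' @param filter_window width (odd) of the moving-window temporal
#'   filter.
#' @param excluded_destination_classes semantic class names whose
#'   appearance after the stable window excludes the pixel (conversion,
#'   not abandonment).
#' @return object of class `abandonment_params`.
#' @export
abandonment_params <- function(min_fallow_years = 5,
                               stable_years = 1992:1997,
                               filter_window = 5,
                               excluded_destination_classes =
                                 c("built_up", "wetland")) {
  stopifnot(min_fallow_years >= 1)
  if (filter_window %% 2 == 0) {
    stop("`filter_window` must be odd", call. = FALSE)
  }
  structure(list(min_fallow_years = as.integer(min_fallow_years),
                 stable_years = as.integer(stable_years),
                 filter_window = as.integer(filter_window),
                 excluded_destination_classes = excluded_destination_classes),
            class = "abandonment_params")
}

#' Moving-window temporal filter for class time series
#'
#' Removes single-year (and generally minority) misclassifications: for
#' each pixel-year, if the class differs from the modal class of the
#' centered window and that mode is held by a strict majority of the
#' window (>= 3 of 5 years for the default width), the year is
#' reassigned to the mode. The series is padded at both ends by edge
#' replication, so output length equals input length. Runs at least as
#' long as the majority count are never erased.
#'
#' @param series a `landcover_series`, or an integer matrix
#'   (pixels x years).
#' @param window odd window width, at most the series length.
#' @return same type as the input, filtered.
#' @examples
#' m <- matrix(c(1, 1, 9, 1, 1), nrow = 1)
#' temporal_filter(m, 5)  # isolated deviation removed
#' @export
temporal_filter <- function(series, window = 5) {
  is_series <- inherits(series, "landcover_series")
  cls <- if (is_series) series$classes else series
  ny <- ncol(cls)
  if (window %% 2 == 0) stop("`window` must be odd", call. = FALSE)
  if (window > ny) stop("`window` longer than the series", call. = FALSE)
  if (window == 1) return(series)
  half <- (window - 1L) %/% 2L
  majority <- half + 1L  # strict majority of the window
  codes <- sort(unique(as.vector(cls)))
  out <- cls
  # padded year index with edge replication
  pad_idx <- function(i) pmin(pmax(i, 1L), ny)
  for (y in seq_len(ny)) {
    win <- cls[, pad_idx((y - half):(y + half)), drop = FALSE]
    counts <- vapply(codes, function(cd) rowSums(win == cd), numeric(nrow(cls)))
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
    top <- max.col(counts, ties.method = "first")
    topn <- counts[cbind(seq_len(nrow(cls)), top)]
    mode_code <- codes[top]
    flip <- topn >= majority & mode_code != cls[, y]
    out[flip, y] <- mode_code[flip]
  }
  if (is_series) {
    series$classes <- out
    series
  } else {
    out
  }
}

# Aggregate cropland and return a logical cropland matrix plus the raw
# (aggregated) class matrix used for destination checks.
prepare_series <- function(series, params) {
  agg <- aggregate_cropland(series)
  excl_codes <- agg$codebook$code[
    agg$codebook$class %in% params$excluded_destination_classes
  ]
  list(cls = agg$classes, crop = agg$classes == 1L, excl = excl_codes,
       years = agg$years)
}

#' Detect abandoned cropland from a filtered land-cover series
#'
#' Applies the decision rules to each pixel of an already
#' temporally-filtered series (all cropland classes are merged first):
#'
#' * `never_cropland` — not cropland throughout the stable window
#'   (pixels that were never, or never stably, cropland are not
#'   eligible);
#' * `converted_excluded` — an excluded destination class (built-up,
#'   wetland) appears in any year after the stable window: conversion,
#'   not abandonment;
#' * `abandoned` — stable cropland whose non-cropland run of at least
#'   `min_fallow_years` persists to the end of the series;
#'   `abandon_year` is the first non-cropland year;
#' * `recultivated_excluded` — a qualifying (>= `min_fallow_years`)
#'   non-cropland run is followed by at least one cropland year;
#' * `stable_cropland` — everything else that is historically stable
#'   cropland, including short-term fallow (runs shorter than
#'   `min_fallow_years`, which are skipped rather than classified) and
#'   conversions too recent to satisfy the fallow rule.
#'
#' @param series a `landcover_series` (apply [temporal_filter()] first;
#'   this function does not filter).
#' @param params an [abandonment_params()].
#' @return object of class `abandonment_map`: list with `status`
#'   (factor), `abandon_year`, `fallow_run_length` (both `NA` except on
#'   abandoned pixels), and `spec`.
#' @export
detect_abandonment <- function(series, params = abandonment_params()) {
  years <- series$years
  if (!all(params$stable_years %in% years)) {
    stop("`stable_years` must lie inside the series years", call. = FALSE)
  }
  pr <- prepare_series(series, params)
  np <- nrow(pr$cls)
  ny <- length(years)
  stable_idx <- match(params$stable_years, years)
  after_idx <- seq(max(stable_idx) + 1L, ny)

  stable <- rowSums(pr$crop[, stable_idx, drop = FALSE]) == length(stable_idx)
  status <- rep("never_cropland", np)
  abandon_year <- rep(NA_integer_, np)
  fallow_len <- rep(NA_integer_, np)
  status[stable] <- "stable_cropland"

  if (length(pr$excl) > 0) {
    has_excl <- rowSums(matrix(pr$cls[, after_idx, drop = FALSE] %in% pr$excl,
                               nrow = np)) > 0
    status[stable & has_excl] <- "converted_excluded"
  }

  todo <- which(status == "stable_cropland")
  min_f <- params$min_fallow_years
  for (p in todo) {
    cr <- pr$crop[p, ]
    y <- max(stable_idx) + 1L
    while (y <= ny) {
      if (cr[y]) { y <- y + 1L; next }
      run_end <- y
      while (run_end < ny && !cr[run_end + 1L]) run_end <- run_end + 1L
      len <- run_end - y + 1L
      if (run_end == ny) {
        if (len >= min_f) {
          status[p] <- "abandoned"
          abandon_year[p] <- years[y]
          fallow_len[p] <- len
        }
        break
      }
      if (len >= min_f) {
        status[p] <- "recultivated_excluded"
        break
      }
      y <- run_end + 1L  # short-term fallow: skip, keep scanning
    }
  }

  structure(list(
    status = factor(status, levels = c("never_cropland", "stable_cropland",
                                       "abandoned", "recultivated_excluded",
                                       "converted_excluded")),
    abandon_year = abandon_year,
    fallow_run_length = fallow_len,
    params = params,
    spec = series$spec
  ), class = "abandonment_map")
}

#' @export
print.abandonment_map <- function(x, ...) {
  cat("<abandonment_map>\n")
  print(table(x$status))
  invisible(x)
}

#' Historically recultivated cropland (suitability-model presence layer)
#'
#' A pixel is a recultivation presence when it was historically stable
#' cropland and a non-cropland run of at least `min_fallow_years` is
#' followed by at least one cropland year — i.e. it was abandoned by
#' the fallow rule and then returned to production. This layer is the
#' training presence for the recultivation-suitability model.
#'
#' @inheritParams detect_abandonment
#' @return logical vector over pixels.
#' @export
detect_recultivation_presence <- function(series,
                                          params = abandonment_params()) {
  years <- series$years
  pr <- prepare_series(series, params)
  np <- nrow(pr$cls)
  ny <- length(years)
  stable_idx <- match(params$stable_years, years)
  stable <- rowSums(pr$crop[, stable_idx, drop = FALSE]) == length(stable_idx)
  min_f <- params$min_fallow_years
  out <- rep(FALSE, np)
  for (p in which(stable)) {
    cr <- pr$crop[p, ]
    y <- max(stable_idx) + 1L
    while (y <= ny) {
      if (cr[y]) { y <- y + 1L; next }
      run_end <- y
      while (run_end < ny && !cr[run_end + 1L]) run_end <- run_end + 1L
      if (run_end < ny && run_end - y + 1L >= min_f) {
        out[p] <- TRUE
        break
      }
      y <- run_end + 1L
    }
  }
  out
}

#' Average annual abandonment rate
#'
#' Total abandoned area divided by the length of the observation
#' period.
#'
#' @param map an `abandonment_map`.
#' @param spec the shared [grid_spec()].
#' @return rate in Mha per year.
#' @seealso [area_rate()] for the same quantity from a printed area.
#' @export
abandonment_rate <- function(map, spec = map$spec) {
  area_mha <- sum(map$status == "abandoned") * spec$pixel_area / 1e6
  area_rate(area_mha, spec$year_start, spec$year_end)
}

#' @param area_mha total abandoned area in Mha.
#' @param year_start,year_end observation period.
#' @rdname abandonment_rate
#' @export
area_rate <- function(area_mha, year_start, year_end) {
  if (year_end <= year_start) {
    stop("zero-length observation period", call. = FALSE)
  }
  area_mha / (year_end - year_start)
}

#' Summarize an abandonment map as areas
#'
#' @param map an `abandonment_map`.
#' @return data.frame with per-status pixel counts and areas (Mha).
#' @export
abandonment_summary <- function(map) {
  tab <- table(map$status)
  data.frame(status = names(tab),
             pixels = as.integer(tab),
             area_mha = as.numeric(tab) * map$spec$pixel_area / 1e6,
             row.names = NULL)
}
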