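#' Define the shared grid for all co-registered layers
#'
#' Every layer in an analysis (land-cover series, environment stack,
#' abandonment map, allocation) is defined on one common grid so that
#' shape mismatches are impossible by construction. In synthetic mode
#' all pixels have the same area; the 9 ha default is the nominal area
#' of a 300-m pixel.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param pixel_area area of one pixel in hectares (> 0).
#' @param year_start,year_end first and last calendar year of the
#'   annual land-cover record (`year_start < year_end`).
#' @param seed integer seed from which all synthetic layers on this
#'   grid are generated.
#' @return An object of class `grid_spec`.
#' @examples
#' spec <- grid_spec(64, 64, seed = 1)
#' n_pixels(spec)
#' @export
grid_spec <- function(n_rows, n_cols, pixel_area = 9,
                      year_start = 1992, year_end = 2020, seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, pixel_area > 0)
  if (year_start >= year_end) {
    stop("`year_start` must be before `year_end`", call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_area = pixel_area,
         year_start = as.integer(year_start),
         year_end = as.integer(year_end),
         seed = as.integer(seed)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels (%.1f ha each), years %d-%d, seed %d\n",
              x$n_rows, x$n_cols, x$pixel_area, x$year_start, x$year_end, x$seed))
  invisible(x)
}

#' Number of pixels and year vector of a grid
#'
#' Pixels are indexed row-major: pixel `p` sits at row
#' `(p - 1) %/% n_cols + 1`, column `(p - 1) %% n_cols + 1`.
#'
#' @param spec a [grid_spec()].
#' @return `n_pixels()`: integer pixel count. `grid_years()`: integer
#'   vector of calendar years.
#' @export
n_pixels <- function(spec) spec$n_rows * spec$n_cols

#' @rdname n_pixels
#' @export
grid_years <- function(spec) spec$year_start:spec$year_end

# row-major vector <-> matrix (R matrices are column-major)
field_as_matrix <- function(values, spec) {
  matrix(values, nrow = spec$n_rows, ncol = spec$n_cols, byrow = TRUE)
}

matrix_as_field <- function(m) as.vector(t(m))

#' Spatially autocorrelated random field
#'
#' Gaussian-kernel-smoothed white noise plus an optional linear spatial
#' gradient, standardized to zero mean and unit variance. This is the
#' texture model for all synthetic surfaces (productivity, sequestration
#' rates, covariates): any autocorrelated field with a controllable
#' large-scale gradient suffices for the prioritization analyses, so a
#' smoothed-noise field is used rather than a parametric geostatistical
#' model.
#'
#' @param spec a [grid_spec()].
#' @param sigma Gaussian kernel standard deviation in pixels; `0` gives
#'   unsmoothed white noise.
#' @param gradient_strength number in `[-1, 1]`; weight of a linear
#'   west-to-east ramp relative to the noise component. Negative values
#'   reverse the ramp (east-to-west), so two fields built with opposite
#'   signs have opposing spatial trends.
#' @param gradient_axis `"x"` (default, across columns) or `"y"`.
#' @return numeric vector of length `n_pixels(spec)` with mean 0 and
#'   standard deviation 1 (exactly 0 everywhere only if the grid is a
#'   single pixel).
#' @export
gaussian_field <- function(spec, sigma = 3, gradient_strength = 0,
                           gradient_axis = c("x", "y")) {
  gradient_axis <- match.arg(gradient_axis)
  stopifnot(abs(gradient_strength) <= 1)
  z <- matrix(stats::rnorm(n_pixels(spec)), nrow = spec$n_rows)
  z <- smooth_matrix(z, sigma)
  z <- standardize(z)
  if (gradient_strength != 0) {
    ramp <- if (gradient_axis == "x") {
      matrix(rep(seq(-1, 1, length.out = spec$n_cols), each = spec$n_rows),
             nrow = spec$n_rows)
    } else {
      matrix(rep(seq(-1, 1, length.out = spec$n_rows), times = spec$n_cols),
             nrow = spec$n_rows)
    }
    g <- abs(gradient_strength)
    z <- sign(gradient_strength) * g * standardize(ramp) +
      sqrt(1 - g^2) * z
    z <- standardize(z)
  }
  matrix_as_field(z)
}

standardize <- function(m) {
  s <- stats::sd(m)
  if (is.na(s) || s == 0) return(m - mean(m))
  (m - mean(m)) / s
}

# Separable Gaussian smoothing with edge renormalization (zero padding
# divided by the smoothed indicator), so edge pixels are unbiased.
smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  ones <- matrix(1, nrow(m), ncol(m))
  conv1d <- function(x, along) {
    out <- matrix(0, nrow(x), ncol(x))
    for (k in seq_along(w)) {
      off <- k - r - 1L
      out <- out + w[k] * shift_matrix(x, off, along)
    }
    out
  }
  num <- conv1d(conv1d(m, "row"), "col")
  den <- conv1d(conv1d(ones, "row"), "col")
  num / den
}

shift_matrix <- function(m, off, along) {
  if (off == 0) return(m)
  out <- matrix(0, nrow(m), ncol(m))
  dim_len <- if (along == "row") nrow(m) else ncol(m)
  if (abs(off) >= dim_len) return(out)
  if (along == "row") {
    if (off > 0) out[(1 + off):nrow(m), ] <- m[1:(nrow(m) - off), , drop = FALSE]
    else out[1:(nrow(m) + off), ] <- m[(1 - off):nrow(m), , drop = FALSE]
  } else {
    if (off > 0) out[, (1 + off):ncol(m)] <- m[, 1:(ncol(m) - off), drop = FALSE]
    else out[, 1:(ncol(m) + off)] <- m[, (1 - off):ncol(m), drop = FALSE]
  }
  out
}

#' Read and write single-band grids as ESRI ASCII rasters
#'
#' Layers are exchanged one band per file in the ESRI ASCII grid
#' format (`.asc`), a plain-text raster format readable by GDAL and
#' standard GIS tools. Class-coded grids are written as integers with a
#' nodata code; continuous grids as floating point.
#'
#' @param values numeric vector of length `n_pixels(spec)`, row-major.
#' @param spec the shared [grid_spec()].
#' @param path file path ending in `.asc`.
#' @param nodata value substituted for `NA`.
#' @return `write_grid_asc()` returns `path` invisibly; `read_grid_asc()`
#'   returns a list with `values` (row-major, `NA` where nodata),
#'   `n_rows`, `n_cols`, `cellsize`.
#' @export
write_grid_asc <- function(values, spec, path, nodata = -9999) {
  stopifnot(length(values) == n_pixels(spec))
  m <- field_as_matrix(values, spec)
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  # cellsize in degrees is irrelevant in synthetic mode; the side of a
  # square pixel in metres is recorded so areas round-trip.
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.6f", sqrt(spec$pixel_area * 1e4)),
    sprintf("NODATA_value %s", format(nodata, scientific = FALSE))
  ), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_asc
#' @export
read_grid_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  keys <- tolower(vapply(kv, `[[`, "", 1))
  vals <- as.numeric(vapply(kv, `[[`, "", 2))
  names(vals) <- keys
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == vals[["nodata_value"]]] <- NA
  list(values = matrix_as_field(m),
       n_rows = as.integer(vals[["nrows"]]),
       n_cols = as.integer(vals[["ncols"]]),
       cellsize = vals[["cellsize"]])
}

# Run a block with a temporary RNG state seeded from `seed`, restoring
# the caller's state afterwards so library functions never clobber the
# global stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# round half away from zero (display convention for integer percents)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
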