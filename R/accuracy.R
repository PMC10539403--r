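#' Disproportionate stratified validation sample
#'
#' Draws an equal-count random sample per map class (without
#' replacement) — the design of choice for validating small map
#' classes such as abandoned cropland, since proportional sampling
#' would starve the rare class.
#'
#' @param map_class factor (or character) vector over pixels giving
#'   each pixel's mapped class; for a two-stratum abandonment design
#'   see [binary_map_class()].
#' @param n_per_stratum samples per map class.
#' @param seed integer seed; the draw is reproducible.
#' @return data.frame with `pixel` and `map_class`, `n_per_stratum`
#'   rows per class.
#' @export
stratified_sample <- function(map_class, n_per_stratum, seed = 1L) {
  map_class <- as.factor(map_class)
  strata <- levels(map_class)
  sizes <- table(map_class)
  small <- sizes < n_per_stratum
  if (any(small)) {
    stop("stratum ", paste(names(sizes)[small], collapse = ", "),
         " has only ", paste(sizes[small], collapse = ", "),
         " pixels (need ", n_per_stratum, ")", call. = FALSE)
  }
  if (n_per_stratum == 0) {
    return(data.frame(pixel = integer(), map_class = factor(character(),
                                                            levels = strata)))
  }
  with_seed(seed, {
    rows <- lapply(strata, function(s) {
      data.frame(pixel = resample(which(map_class == s), n_per_stratum),
                 map_class = factor(s, levels = strata))
    })
    do.call(rbind, rows)
  })
}

#' Collapse an abandonment map to the two validation strata
#'
#' @param map an `abandonment_map`.
#' @return factor over pixels with levels `abandoned`, `not_abandoned`.
#' @export
binary_map_class <- function(map) {
  factor(ifelse(map$status == "abandoned", "abandoned", "not_abandoned"),
         levels = c("abandoned", "not_abandoned"))
}

#' Stratum weights (map-class area proportions)
#'
#' @param map_class factor over pixels.
#' @return named numeric vector of class area proportions, summing
#'   to 1.
#' @export
strata_weights <- function(map_class) {
  tab <- table(map_class)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

# proportion-based confusion matrix p_ij = W_i * n_ij / n_i
proportion_matrix <- function(samples, weights) {
  samples$map_class <- factor(samples$map_class, levels = names(weights))
  samples$reference_class <- factor(samples$reference_class,
                                    levels = names(weights))
  n <- table(samples$map_class, samples$reference_class)
  ni <- rowSums(n)
  if (any(ni == 0)) {
    stop("every stratum needs at least one sample", call. = FALSE)
  }
  p <- sweep(n / ni, 1, weights, "*")
  list(p = p, n = n, ni = ni)
}

#' Stratified confusion-matrix accuracy metrics
#'
#' Converts the sample confusion counts into area-proportion form
#' (`p_ij = W_i n_ij / n_i`, the standard stratified estimator for map
#' accuracy assessment) and reports overall accuracy, and per-class
#' user's accuracy, producer's accuracy and their harmonic mean (F1).
#'
#' @param samples data.frame with `map_class` and `reference_class`.
#' @param weights named stratum weights (see [strata_weights()]); names
#'   define the class set.
#' @param focus class for the scalar `users_accuracy` /
#'   `producers_accuracy` / `f1` entries (default the first class,
#'   conventionally `abandoned`).
#' @return object of class `accuracy_report` (a list):
#'   `overall_accuracy`, `users_accuracy`, `producers_accuracy`, `f1`
#'   (for `focus`), per-class vectors `ua`, `pa`, the proportion matrix
#'   `p`, counts `n`, and `weights`. A class absent from the reference
#'   labels gets `NA` producer's accuracy with a warning.
#' @export
confusion_metrics <- function(samples, weights, focus = names(weights)[1]) {
  pm <- proportion_matrix(samples, weights)
  p <- pm$p
  oa <- sum(diag(p))
  ua <- diag(p) / rowSums(p)
  pa_den <- colSums(p)
  if (any(pa_den == 0)) {
    warning("class absent from reference labels; producer's accuracy ",
            "undefined", call. = FALSE)
  }
  pa <- ifelse(pa_den > 0, diag(p) / pa_den, NA_real_)
  names(pa) <- names(pa_den)
  f1 <- f1_score(ua[[focus]], pa[[focus]])
  structure(list(overall_accuracy = oa,
                 users_accuracy = ua[[focus]],
                 producers_accuracy = pa[[focus]],
                 f1 = f1, ua = ua, pa = pa,
                 p = p, n = pm$n, weights = weights, focus = focus),
            class = "accuracy_report")
}

#' Harmonic mean of user's and producer's accuracy
#'
#' @param ua,pa user's and producer's accuracy in `[0, 1]`.
#' @return F1 score.
#' @examples
#' f1_score(0.95, 0.77)
#' @export
f1_score <- function(ua, pa) {
  if (is.na(ua) || is.na(pa) || ua + pa == 0) return(NA_real_)
  2 * ua * pa / (ua + pa)
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> OA %.3f | %s: UA %.3f PA %.3f F1 %.3f\n",
              x$overall_accuracy, x$focus, x$users_accuracy,
              x$producers_accuracy, x$f1))
  invisible(x)
}

#' Error-adjusted class areas with confidence intervals
#'
#' Re-estimates each class's area from the probability-weighted
#' confusion matrix rather than by pixel counting:
#' `area_j = total_area * sum_i W_i n_ij / n_i`, with the stratified
#' standard error
#' `SE(p_j) = sqrt( sum_i W_i^2 (n_ij/n_i)(1 - n_ij/n_i) / (n_i - 1) )`
#' and a normal-approximation 95% interval (`1.96 * SE`). No
#' finite-population correction is applied (sampled fractions of the
#' map are tiny). Estimated class areas sum exactly to `total_area`.
#'
#' @param samples data.frame with `map_class`, `reference_class`.
#' @param weights named stratum weights.
#' @param total_area total map area (any unit; outputs share it).
#' @return data.frame, one row per class: `class`, `mapped_area`,
#'   `area`, `se`, `ci95`.
#' @export
error_adjusted_area <- function(samples, weights, total_area) {
  pm <- proportion_matrix(samples, weights)
  if (any(pm$ni < 2)) {
    stop("a stratum with a single sample has undefined variance",
         call. = FALSE)
  }
  nprop <- pm$n / pm$ni            # n_ij / n_i
  p_j <- colSums(sweep(nprop, 1, weights, "*"))
  var_j <- colSums(sweep(nprop * (1 - nprop), 1,
                         weights^2 / (pm$ni - 1), "*"))
  se_j <- sqrt(var_j)
  data.frame(class = names(p_j),
             mapped_area = as.numeric(weights[names(p_j)]) * total_area,
             area = p_j * total_area,
             se = se_j * total_area,
             ci95 = 1.96 * se_j * total_area,
             row.names = NULL)
}
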