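#' Fit the recultivation-suitability model
#'
#' Presence-background model of recultivation propensity: covariates
#' are standardized to zero mean and unit variance over the whole study
#' region, the historically recultivated pixels form the presence set,
#' and `background_n` pixels drawn uniformly (without replacement, and
#' excluding the presence pixels) form the background. A
#' ridge-regularized logistic model is fit (the regularization handles
#' collinear drivers); its logistic output is the calibrated
#' recultivatability in `[0, 1]`. With a single covariate an
#' unpenalized logistic fit is used.
#'
#' Background subsampling shifts only the intercept of a logistic
#' model, so coefficient signs and magnitudes are comparable across
#' background sizes; the reported separability score is the
#' rank-statistic AUC on the training sample.
#'
#' @param presence logical vector over pixels (recultivation presence;
#'   see [detect_recultivation_presence()]).
#' @param stack an `env_stack` providing `covariates`.
#' @param background_n number of background pixels (capped at the
#'   number of available non-presence pixels).
#' @param seed integer seed for the background draw; the fit is
#'   deterministic given the seed.
#' @return object of class `recult_model`: `coefficients` (intercept
#'   plus one weight per standardized covariate), `centers`, `scales`,
#'   `auc`, `background_n`, `seed`.
#' @export
fit_recultivation_suitability <- function(presence, stack,
                                          background_n = 10000, seed = 1L) {
  covs <- stack$covariates
  if (is.null(dim(covs))) covs <- matrix(covs, ncol = 1)
  stopifnot(length(presence) == nrow(covs))
  if (!any(presence)) {
    stop("no presence pixels: cannot fit the suitability model", call. = FALSE)
  }
  if (sum(presence) < 20) {
    stop("fewer than 20 presence pixels: fit would be unstable", call. = FALSE)
  }
  if (any(!is.finite(covs))) stop("covariates must be finite", call. = FALSE)

  centers <- colMeans(covs)
  scales <- apply(covs, 2, stats::sd)
  scales[scales == 0] <- 1
  xs <- sweep(sweep(covs, 2, centers), 2, scales, "/")

  pres_idx <- which(presence)
  bg_pool <- which(!presence)
  nb <- min(background_n, length(bg_pool))
  bg_idx <- with_seed(seed, resample(bg_pool, nb))

  x <- xs[c(pres_idx, bg_idx), , drop = FALSE]
  y <- c(rep(1, length(pres_idx)), rep(0, nb))

  if (ncol(x) >= 2 && qr(x)$rank < ncol(x)) {
    warning("collinear covariates; ridge regularization resolves the fit",
            call. = FALSE)
  }

  if (ncol(x) >= 2) {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = 1e-4, standardize = FALSE,
                          thresh = 1e-10)
    beta <- as.numeric(fit$beta)
    intercept <- as.numeric(fit$a0)
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, x), y, family = stats::binomial())
    )
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    intercept <- cf[1]
    beta <- cf[-1]
  }
  coef <- c(intercept = unname(intercept), stats::setNames(
    beta, paste0("covariate_", seq_len(ncol(x)))))

  lin <- as.numeric(x %*% beta) + intercept
  auc <- rank_auc(lin, y == 1)

  structure(list(coefficients = coef, centers = centers, scales = scales,
                 auc = auc, background_n = nb, seed = as.integer(seed)),
            class = "recult_model")
}

# AUC as the Mann-Whitney rank statistic
rank_auc <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.recult_model <- function(x, ...) {
  cat(sprintf("<recult_model> %d covariates, background n = %d, AUC = %.3f\n",
              length(x$coefficients) - 1, x$background_n, x$auc))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict recultivatability over the grid
#'
#' With `tau = NULL` (default) the raw logistic output is returned:
#' the fitted intercept reflects the presence/background mix, so in the
#' no-information case the propensity equals the training prevalence.
#' Presence-background intercepts are not identified at the landscape
#' scale, however, so for thresholding the pipeline uses the
#' conventional default-prevalence calibration of maximum-entropy
#' suitability models: set `tau` (typically 0.5) and the linear
#' predictor is centered over the study region and anchored so that a
#' pixel with average drivers scores `tau`. The 0.2 suitability cut is
#' applied to this calibrated output.
#'
#' @param object a `recult_model`.
#' @param stack an `env_stack` with the same covariate layout the model
#'   was trained on.
#' @param tau optional default prevalence in `(0, 1)` for the
#'   calibrated output; `NULL` keeps the fitted intercept.
#' @param ... unused.
#' @return numeric vector of propensities in `[0, 1]` over all pixels.
#' @export
predict.recult_model <- function(object, stack, tau = NULL, ...) {
  covs <- stack$covariates
  if (is.null(dim(covs))) covs <- matrix(covs, ncol = 1)
  if (ncol(covs) != length(object$centers)) {
    stop("covariate count does not match the fitted model", call. = FALSE)
  }
  xs <- sweep(sweep(covs, 2, object$centers), 2, object$scales, "/")
  beta <- object$coefficients[-1]
  eta <- as.numeric(xs %*% beta)
  if (is.null(tau)) {
    stats::plogis(object$coefficients[["intercept"]] + eta)
  } else {
    stopifnot(tau > 0, tau < 1)
    stats::plogis(stats::qlogis(tau) + eta - mean(eta))
  }
}

#' Classify abandoned pixels into the four suitability types
#'
#' A pixel is recultivation-suitable when its recultivatability is
#' strictly greater than the threshold (default 0.2) *and* it lies
#' outside protected areas; it is reforestation-suitable when its
#' potential natural vegetation is forest or woodland (the
#' protected-area mask does not restrict natural regrowth). The cross
#' of the two booleans gives the typology `recult_only`,
#' `reforest_only`, `both`, `neither`, defined on abandoned pixels
#' only.
#'
#' @param recultivability propensity grid in `[0, 1]` (from
#'   [predict.recult_model()], or a precomputed suitability grid from an
#'   external model).
#' @param stack an `env_stack` with `pnv_class`, `pnv_forest_codes`,
#'   `protected`.
#' @param map an `abandonment_map`.
#' @param threshold recultivatability cut in `(0, 1)`; strictly-greater
#'   comparison.
#' @return object of class `suitability_types`: `recultivability`,
#'   `type` (factor, `NA` off abandoned pixels), `recult_suitable`,
#'   `reforest_suitable` (logical, `FALSE` off abandoned pixels),
#'   `threshold`, `spec`.
#' @export
classify_suitability <- function(recultivability, stack, map,
                                 threshold = 0.2) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(stack$pnv_class)) {
    stop("missing PNV layer in the environment stack", call. = FALSE)
  }
  np <- length(map$status)
  stopifnot(length(recultivability) == np,
            length(stack$pnv_class) == np,
            length(stack$protected) == np)
  abandoned <- map$status == "abandoned"
  rec <- abandoned & recultivability > threshold & !stack$protected
  ref <- abandoned & stack$pnv_class %in% stack$pnv_forest_codes
  type <- rep(NA_character_, np)
  type[abandoned] <- ifelse(rec[abandoned],
                            ifelse(ref[abandoned], "both", "recult_only"),
                            ifelse(ref[abandoned], "reforest_only", "neither"))
  structure(list(
    recultivability = recultivability,
    type = factor(type, levels = c("recult_only", "reforest_only",
                                   "both", "neither")),
    recult_suitable = rec,
    reforest_suitable = ref,
    threshold = threshold,
    spec = map$spec
  ), class = "suitability_types")
}

#' @export
print.suitability_types <- function(x, ...) {
  cat(sprintf("<suitability_types> threshold %.2f\n", x$threshold))
  print(table(x$type, useNA = "ifany"))
  invisible(x)
}

#' Suitability-typology shares from areas
#'
#' Converts the areas suitable for recultivation, reforestation, and
#' both (plus the abandoned total) into the percentage shares of the
#' four types, as reported in typology donut charts.
#'
#' @param area_recult,area_reforest,area_both,area_total areas in a
#'   common unit; `area_both` is the overlap of the first two and
#'   `area_total` the whole abandoned extent.
#' @return named numeric vector of percentages (`recult_only`,
#'   `reforest_only`, `both`, `neither`), summing to 100.
#' @examples
#' typology_shares(61, 83, 50, 101)
#' @export
typology_shares <- function(area_recult, area_reforest, area_both,
                            area_total) {
  stopifnot(area_both <= area_recult, area_both <= area_reforest,
            area_total >= area_recult + area_reforest - area_both)
  ro <- area_recult - area_both
  fo <- area_reforest - area_both
  ne <- area_total - ro - fo - area_both
  100 * c(recult_only = ro, reforest_only = fo, both = area_both,
          neither = ne) / area_total
}
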