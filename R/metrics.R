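#' Paired predicted/actual observations
#'
#' Validates a pair of prediction and reference vectors for the accuracy
#' statistics. `m` holds the method's predicted values, `e` the actual
#' (manually measured) values.
#'
#' @param m numeric vector of predicted values.
#' @param e numeric vector of actual values, same length.
#' @return A list with `m`, `e`, `n`.
#' @export
paired_observations <- function(m, e) {
  if (length(m) != length(e)) {
    stop("'m' and 'e' must have equal length", call. = FALSE)
  }
  if (anyNA(m) || anyNA(e)) stop("observations contain NA", call. = FALSE)
  list(m = as.numeric(m), e = as.numeric(e), n = length(m))
}

#' Coefficient of determination
#'
#' \deqn{R^2 = 1 - \sum_j (m_j - e_j)^2 / \sum_j (m_j - \bar m)^2}
#' where \eqn{\bar m} is the mean of the *predicted* values. Note the
#' denominator is centered on the predictions, not the conventional
#' centering on the actuals; `standard = TRUE` computes the conventional
#' form (residuals and centering on `e`) for comparison.
#'
#' @param m predicted values (length >= 2, not constant).
#' @param e actual values.
#' @param standard use the conventional definition instead.
#' @return R-squared.
#' @export
r_squared <- function(m, e, standard = FALSE) {
  obs <- paired_observations(m, e)
  if (obs$n < 2) stop("need at least 2 observations", call. = FALSE)
  if (standard) {
    den <- sum((obs$e - mean(obs$e))^2)
    if (den == 0) stop("actual values are constant: R^2 undefined", call. = FALSE)
    return(1 - sum((obs$m - obs$e)^2) / den)
  }
  den <- sum((obs$m - mean(obs$m))^2)
  if (den == 0) stop("predicted values are constant: R^2 undefined", call. = FALSE)
  1 - sum((obs$m - obs$e)^2) / den
}

#' Root mean square error
#'
#' \deqn{RMSE = \sqrt{\sum_j (m_j - e_j)^2 / n}}
#'
#' @inheritParams r_squared
#' @return RMSE, in the units of the inputs.
#' @export
rmse <- function(m, e) {
  obs <- paired_observations(m, e)
  if (obs$n < 1) stop("need at least 1 observation", call. = FALSE)
  sqrt(sum((obs$m - obs$e)^2) / obs$n)
}

#' Mean absolute percentage error
#'
#' \deqn{MAPE = \frac{1}{n}\sum_j |e_j - m_j| / m_j}
#' with the *predicted* value in the denominator (the conventional form
#' divides by the actual; `standard = TRUE` reports that instead).
#' Returned as a fraction; multiply by 100 to report percent.
#'
#' @inheritParams r_squared
#' @return MAPE as a fraction.
#' @export
mape <- function(m, e, standard = FALSE) {
  obs <- paired_observations(m, e)
  den <- if (standard) obs$e else obs$m
  if (any(den == 0)) {
    stop(sprintf("denominator value is 0 at index %d: MAPE undefined",
                 which(den == 0)[1]), call. = FALSE)
  }
  mean(abs(obs$e - obs$m) / den)
}

#' Evaluate predictions
#'
#' Bundles the three accuracy statistics into one report.
#'
#' @inheritParams r_squared
#' @param standard additionally include the conventional forms.
#' @return An `evaluation_report`: list with `r2`, `rmse`, `mape`, `n`
#'   (and `r2_standard`, `mape_standard` when requested).
#' @export
evaluate_predictions <- function(m, e, standard = FALSE) {
  rep <- list(r2 = r_squared(m, e), rmse = rmse(m, e), mape = mape(m, e),
              n = length(m))
  if (standard) {
    rep$r2_standard <- r_squared(m, e, standard = TRUE)
    rep$mape_standard <- mape(m, e, standard = TRUE)
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d | R^2 = %.4f | RMSE = %.4g | MAPE = %.2f%%\n",
              x$n, x$r2, x$rmse, 100 * x$mape))
  invisible(x)
}

#' Dark-ratio threshold sweep
#'
#' Re-classifies every grain at each candidate dark-ratio threshold,
#' counts filled grains per panicle, and scores the predicted counts
#' against the actual filled counts. Thresholds above the optimum
#' misclassify filled grains as unfilled (underestimation); thresholds
#' below it absorb dark-leaning unfilled grains (overestimation).
#'
#' @param dr_by_panicle list of numeric vectors: per-grain dark ratios,
#'   one vector per panicle (>= 2 panicles).
#' @param truth_filled numeric vector of actual filled counts, one per
#'   panicle.
#' @param thresholds candidate thresholds in (0, 1) (default
#'   `c(0.4, 0.6, 0.7, 0.8)`).
#' @return A data.frame ordered by threshold: `threshold`, `r2`, `rmse`,
#'   `mean_error` (mean predicted minus actual; positive =
#'   overestimation), plus attribute `predicted` (matrix of per-panicle
#'   predicted counts, one column per threshold).
#' @export
threshold_sweep <- function(dr_by_panicle, truth_filled,
                            thresholds = c(0.4, 0.6, 0.7, 0.8)) {
  if (length(dr_by_panicle) < 2) {
    stop("need at least 2 panicles", call. = FALSE)
  }
  if (length(dr_by_panicle) != length(truth_filled)) {
    stop("panicle count mismatch between detections and truth", call. = FALSE)
  }
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  thresholds <- sort(thresholds)
  pred <- vapply(thresholds, function(th) {
    vapply(dr_by_panicle, function(drs) sum(drs > th), numeric(1))
  }, numeric(length(dr_by_panicle)))
  pred <- matrix(pred, ncol = length(thresholds))
  res <- data.frame(
    threshold = thresholds,
    r2 = apply(pred, 2, function(p) {
      # constant predictions (e.g. a threshold above every dark ratio)
      # leave the denominator of the printed form empty
      tryCatch(r_squared(p, truth_filled), error = function(e) NA_real_)
    }),
    rmse = apply(pred, 2, function(p) rmse(p, truth_filled)),
    mean_error = apply(pred, 2, function(p) mean(p - truth_filled)))
  colnames(pred) <- format(thresholds)
  attr(res, "predicted") <- pred
  res
}
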