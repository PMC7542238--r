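# Six regression error measures, per ROI and aggregated.

METRIC_NAMES <- c("MAE", "RMSE", "MeAE", "MAPE", "R2", "RMSPE")

#' Compute a single regression error measure
#'
#' Implements the six measures used to judge ROI prediction quality:
#' \itemize{
#'   \item `MAE` — mean absolute error, \eqn{\frac1n \sum |f_i - y_i|}
#'   \item `RMSE` — root mean square error,
#'     \eqn{\sqrt{\frac1n \sum (f_i - y_i)^2}}
#'   \item `MeAE` — median absolute error, \eqn{median |f_i - y_i|}
#'   \item `MAPE` — mean absolute percentage error,
#'     \eqn{\frac{100}{n} \sum |(y_i - f_i)/y_i|}
#'   \item `R2` — coefficient of determination,
#'     \eqn{1 - \sum (y_i - f_i)^2 / \sum (y_i - \bar y)^2}
#'   \item `RMSPE` — root mean square percentage error,
#'     \eqn{\sqrt{\frac1n \sum ((y_i - f_i)/y_i)^2}}
#' }
#' MeAE is taken on the absolute residuals; the measure's name demands the
#' absolute value even where a bare `median(f - y)` is sometimes written.
#' Percentage measures require all \eqn{|y_i|} strictly positive and fail
#' loudly otherwise rather than silently skipping observations; R2 requires
#' a non-constant truth vector.
#'
#' @param name one of `"MAE"`, `"RMSE"`, `"MeAE"`, `"MAPE"`, `"R2"`,
#'   `"RMSPE"`.
#' @param f predicted values.
#' @param y actual values (same length as `f`).
#' @return The measure's value.
#' @export
compute_metric <- function(name, f, y) {
  name <- match.arg(name, METRIC_NAMES)
  if (length(f) != length(y)) stop("predicted and actual vectors differ in length")
  if (length(y) < 1L) stop("need at least one observation")
  e <- f - y
  switch(name,
    MAE = mean(abs(e)),
    RMSE = sqrt(mean(e^2)),
    MeAE = stats::median(abs(e)),
    MAPE = {
      check_nonzero_truth(y)
      100 * mean(abs((y - f) / y))
    },
    RMSPE = {
      check_nonzero_truth(y)
      sqrt(mean(((y - f) / y)^2))
    },
    R2 = {
      ss_tot <- sum((y - mean(y))^2)
      if (ss_tot <= 0) stop("R2 undefined: actual values are constant")
      1 - sum(e^2) / ss_tot
    })
}

check_nonzero_truth <- function(y) {
  bad <- which(abs(y) <= 1e-12)
  if (length(bad) > 0L)
    stop(sprintf("percentage error undefined: actual value ~ 0 at index %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  invisible(TRUE)
}

#' Evaluate predicted against actual phenotypes with all six measures
#'
#' @param pred predicted phenotype matrix (samples x ROIs), same shape and
#'   ROI ids as `actual`.
#' @param actual the observed [phenotype_matrix()].
#' @param n_features_used optional count of feature SNPs behind the
#'   predictions, recorded in the report.
#' @return An object of class `metrics_report`: list with `per_roi`
#'   (ROIs x 6 matrix), `aggregate` (named vector, the unweighted arithmetic
#'   mean over ROIs), and `n_features_used`.
#' @export
evaluate <- function(pred, actual, n_features_used = NA_integer_) {
  pred <- as.matrix(pred); actual <- as.matrix(actual)
  if (!all(dim(pred) == dim(actual))) stop("prediction/actual shape mismatch")
  if (!is.null(colnames(pred)) && !is.null(colnames(actual)) &&
      !identical(colnames(pred), colnames(actual)))
    stop("prediction/actual ROI ids differ")
  q <- ncol(actual)
  per_roi <- matrix(NA_real_, q, length(METRIC_NAMES),
                    dimnames = list(colnames(actual), METRIC_NAMES))
  for (j in seq_len(q))
    for (m in METRIC_NAMES)
      per_roi[j, m] <- compute_metric(m, pred[, j], actual[, j])
  structure(list(per_roi = per_roi,
                 aggregate = colMeans(per_roi),
                 n_features_used = n_features_used),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report over %d ROIs (features used: %s)\n",
              nrow(x$per_roi), x$n_features_used))
  print(round(x$aggregate, 5))
  invisible(x)
}
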