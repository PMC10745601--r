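# The six affinity-regression metrics. The concordance index follows the
# standard DTA-benchmark convention: pairs tied in the true affinity are
# excluded, tied predictions on comparable pairs score 0.5.

#' Concordance index
#'
#' Over all pairs (i, j) with y_true_i != y_true_j: a pair counts 1 when the
#' prediction ordering matches the truth ordering, 0.5 when the predictions
#' are tied, 0 otherwise; the index is the mean over comparable pairs.
#' 0.5 is chance level, 1 perfect ranking.
#'
#' @param yTrue,yPred numeric vectors of equal length >= 2.
#' @return concordance index in [0, 1]; NaN with a warning when all true
#'   values are tied.
#' @export
concordanceIndex <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) < 2) stop("need at least 2 observations")
  dt <- outer(yTrue, yTrue, "-")
  comparable <- upper.tri(dt) & dt != 0
  nPairs <- sum(comparable)
  if (nPairs == 0) {
    warning("all true values tied; concordance index undefined")
    return(NaN)
  }
  dp <- outer(yPred, yPred, "-")
  st <- sign(dt[comparable]); sp <- sign(dp[comparable])
  sum((sp == st) + 0.5 * (sp == 0)) / nPairs
}

#' Compute the six evaluation metrics
#'
#' MAE, RMSE, Pearson correlation, Spearman correlation (average ranks for
#' ties), concordance index and the coefficient of determination
#' R2 = 1 - SSE/SST (can be negative). Zero variance in either vector makes
#' the correlations NaN with a warning.
#'
#' @param yTrue,yPred numeric vectors of equal length >= 2.
#' @return a \linkS4class{MetricsReport}.
#' @export
computeMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  n <- length(yTrue)
  if (n < 2) stop("need at least 2 observations")
  if (!all(is.finite(yTrue)) || !all(is.finite(yPred)))
    stop("inputs must be finite")
  e <- yPred - yTrue
  mae <- mean(abs(e))
  rmse <- sqrt(mean(e^2))
  degenerate <- sd(yTrue) == 0 || sd(yPred) == 0
  if (degenerate) {
    warning("zero variance in inputs; correlation metrics undefined")
    pcc <- NaN; sp <- NaN
  } else {
    pcc <- cor(yTrue, yPred)
    sp <- cor(rank(yTrue), rank(yPred))
  }
  ci <- concordanceIndex(yTrue, yPred)
  sst <- sum((yTrue - mean(yTrue))^2)
  r2 <- if (sst == 0) NaN else 1 - sum(e^2) / sst
  new("MetricsReport", mae = mae, rmse = rmse, pcc = pcc, spearman = sp,
      ci = ci, r2 = r2, n = as.integer(n))
}

#' Write a metrics report as JSON
#'
#' Keys are exactly \code{mae, rmse, pcc, spearman, ci, r2, n}.
#'
#' @param report a \linkS4class{MetricsReport}.
#' @param path output path.
#' @export
writeMetricsJSON <- function(report, path) {
  jsonlite::write_json(metricsAsList(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
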