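# Regression evaluation: RMSE, Pearson and Spearman correlations, computed
# from their textbook definitions (Spearman = Pearson on average ranks).

.pearson <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sqrt(sum(xc * xc))
  sy <- sqrt(sum(yc * yc))
  if (sx == 0 || sy == 0)
    cdr_stop("degenerate_input_error",
             "correlation undefined for a constant vector")
  sum(xc * yc) / (sx * sy)
}

#' Evaluate predictions against observed responses
#'
#' @param predictions numeric vector of predicted ln IC50 values.
#' @param truth numeric vector of observed ln IC50 values, same length.
#' @return Object of class `cdr_metrics`: `rmse`, `pcc`, `scc`, `n`.
#' @examples
#' evaluate(c(1, 2, 3), c(3, 2, 1))  # pcc = scc = -1
#' @export
evaluate <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    cdr_stop("shape_error", "prediction and truth lengths differ (%d vs %d)",
             length(predictions), length(truth))
  if (length(truth) < 2L)
    cdr_stop("degenerate_input_error", "need at least 2 observations")
  if (anyNA(predictions) || anyNA(truth))
    cdr_stop("data_error", "missing values in predictions or truth")
  if (max(truth) == min(truth))
    cdr_stop("degenerate_input_error", "truth vector is constant")
  structure(list(
    rmse = sqrt(mean((predictions - truth)^2)),
    pcc = .pearson(predictions, truth),
    scc = .pearson(rank(predictions, ties.method = "average"),
                   rank(truth, ties.method = "average")),
    n = length(truth)
  ), class = "cdr_metrics")
}

#' @export
print.cdr_metrics <- function(x, ...) {
  cat(sprintf("RMSE %.4f | PCC %.4f | SCC %.4f (n = %d)\n",
              x$rmse, x$pcc, x$scc, x$n))
  invisible(x)
}
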