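# Automated MP/ERP threshold search and quadrant filtering of scored
# classification records (selective prediction).
#
# The threshold search deliberately uses the correct/incorrect outcome of
# each record: it walks a grid and returns the most conservative (largest)
# threshold that discards at most a set fraction of the correctly
# classified records.  The two axes (MP and ERP) are searched
# independently and combined afterwards into quadrants.

thresholdGrid <- function(step) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a positive scalar", call. = FALSE)
  round(seq(0, 1, by = step), 10)
}

assertScored <- function(records) {
  need <- c("true_label", "pred_label", "mp", "erp")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("records are not scored; missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(records)
}

#' Find the most conservative filtering threshold on one uncertainty axis
#'
#' Walks the grid `{0, step, 2*step, ..., 1}` and returns the largest
#' threshold `t` such that the number of \emph{correctly} classified
#' records with metric value `< t` stays at or below
#' `loss_frac * n_correct` -- i.e. the strictest filter the analyst can
#' apply while discarding at most the stated fraction of correct results.
#' Returns 0 when no positive grid value qualifies.
#'
#' Note that the search looks at the correctness labels of the records it
#' is tuning on; this is a property of the procedure itself, and thresholds
#' should be interpreted accordingly.
#'
#' @param records scored record table (see [scoreRecords()]).
#' @param metric `"mp"` or `"erp"`.
#' @param loss_frac maximum fraction of correct records the filter may
#'   discard, in `[0, 1)`; default 0.01.
#' @param step grid resolution; default 0.01.
#' @return a single threshold value on the grid.
#' @export
findThreshold <- function(records, metric = c("mp", "erp"),
                          loss_frac = 0.01, step = 0.01) {
  metric <- match.arg(metric)
  assertScored(records)
  if (loss_frac < 0 || loss_frac >= 1)
    stop("loss_frac must lie in [0, 1)", call. = FALSE)
  correct <- records$pred_label == records$true_label
  if (!any(correct))
    stop("no correctly classified records: threshold undefined", call. = FALSE)
  vals <- records[[metric]][correct]
  budget <- loss_frac * length(vals)
  grid <- thresholdGrid(step)
  # number of correct records lost is non-decreasing in t, so the feasible
  # set is a prefix of the grid
  lost <- vapply(grid, function(t) sum(vals < t), numeric(1))
  ok <- grid[lost <= budget]
  if (length(ok) == 0L) 0 else max(ok)
}

#' Find MP and ERP thresholds independently
#'
#' Applies [findThreshold()] per axis and packages the result.
#'
#' @inheritParams findThreshold
#' @return an object of class `cropThresholds`: list with `mp_thr`,
#'   `erp_thr`, `loss_frac`, `step`.
#' @export
findThresholds <- function(records, loss_frac = 0.01, step = 0.01) {
  out <- list(
    mp_thr = findThreshold(records, "mp", loss_frac, step),
    erp_thr = findThreshold(records, "erp", loss_frac, step),
    loss_frac = loss_frac,
    step = step
  )
  class(out) <- "cropThresholds"
  out
}

#' @export
print.cropThresholds <- function(x, ...) {
  cat(sprintf("Quadrant thresholds: MP >= %.2f, ERP >= %.2f (loss_frac %.3g, step %.3g)\n",
              x$mp_thr, x$erp_thr, x$loss_frac, x$step))
  invisible(x)
}

#' Assign each record to an (MP, ERP) quadrant
#'
#' The two thresholds partition the (MP, ERP) plane into four quadrants;
#' a metric value equal to its threshold counts as above.  Numbering:
#' Q1 both above, Q2 ERP only above, Q3 both below, Q4 MP only above.
#'
#' @param records scored record table.
#' @param thresholds a `cropThresholds` object (or list with `mp_thr`,
#'   `erp_thr`).
#' @return factor of quadrant ids (`Q1`--`Q4`), one per record.
#' @export
assignQuadrant <- function(records, thresholds) {
  assertScored(records)
  mp_ok <- records$mp >= thresholds$mp_thr
  erp_ok <- records$erp >= thresholds$erp_thr
  q <- ifelse(mp_ok & erp_ok, "Q1",
       ifelse(!mp_ok & erp_ok, "Q2",
       ifelse(!mp_ok & !erp_ok, "Q3", "Q4")))
  factor(q, levels = c("Q1", "Q2", "Q3", "Q4"))
}

keepRule <- function(method, mp_ok, erp_ok) {
  switch(method,
         QM1 = mp_ok,
         QM2 = erp_ok,
         QM3 = mp_ok & erp_ok,
         QM4 = mp_ok | erp_ok,
         stop("unknown quadrant method: ", method, call. = FALSE))
}

#' Filter records with one of the four quadrant methods
#'
#' Keep-rules: QM1 keeps records with MP at or above its threshold, QM2
#' uses the ERP axis only, QM3 requires both and QM4 at least one, so the
#' kept sets nest: QM3 within QM1 and QM2, each within QM4.
#'
#' @param records scored record table.
#' @param thresholds a `cropThresholds` object.
#' @param method one of `"QM1"`, `"QM2"`, `"QM3"`, `"QM4"`.
#' @return list with `kept` and `removed` record tables and `report`: the
#'   thresholds, the per-quadrant correct/incorrect counts and the counts
#'   of correct/incorrect records removed.
#' @export
applyQuadrantMethod <- function(records, thresholds,
                                method = c("QM3", "QM1", "QM2", "QM4")) {
  method <- match.arg(method)
  assertScored(records)
  mp_ok <- records$mp >= thresholds$mp_thr
  erp_ok <- records$erp >= thresholds$erp_thr
  keep <- keepRule(method, mp_ok, erp_ok)
  correct <- records$pred_label == records$true_label
  quad <- assignQuadrant(records, thresholds)
  per_quadrant <- as.data.frame(table(quadrant = quad, correct = correct))
  report <- list(
    method = method,
    mp_thr = thresholds$mp_thr,
    erp_thr = thresholds$erp_thr,
    n = nrow(records),
    n_kept = sum(keep),
    removed_correct = sum(!keep & correct),
    removed_incorrect = sum(!keep & !correct),
    per_quadrant = per_quadrant
  )
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE],
       report = report)
}

#' Sweep a single-axis threshold and track macro-F1 and coverage
#'
#' For each grid value `t`, keeps records with the metric at or above `t`
#' and records the macro-F1 of the kept set together with the number of
#' records remaining.  When no record survives, macro-F1 is `NA`.
#'
#' @param records scored record table.
#' @param metric `"mp"` or `"erp"`.
#' @param grid numeric vector of thresholds (non-empty).
#' @return data frame of class `sweepCurve` with columns `threshold`,
#'   `macro_f1`, `remaining`.
#' @export
thresholdSweep <- function(records, metric = c("mp", "erp"), grid) {
  metric <- match.arg(metric)
  assertScored(records)
  if (missing(grid) || length(grid) == 0L)
    stop("grid must be a non-empty numeric vector", call. = FALSE)
  vals <- records[[metric]]
  rows <- lapply(grid, function(t) {
    kept <- records[vals >= t, , drop = FALSE]
    mf1 <- if (nrow(kept) == 0L) NA_real_ else
      evaluate(confusion(kept))$macro_f1
    data.frame(threshold = t, macro_f1 = mf1, remaining = nrow(kept))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweepCurve", "data.frame")
  out
}
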