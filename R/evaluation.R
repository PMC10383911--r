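# Confusion-matrix construction and the reported metrics: overall accuracy
# (OA), producer/user accuracy (PA = recall, UA = precision), per-class F1
# and macro-F1, class grouping, unfavorable-condition reports, dataset
# tallies, and the resolution-accuracy regression.

#' Build a confusion matrix from labelled records
#'
#' Rows are true classes, columns predicted classes.  When every label
#' belongs to the 12 LC1 codes the canonical LC1 order is used for the
#' classes present; otherwise labels are sorted.  A label outside the
#' declared set is an error naming the offender.
#'
#' @param records data frame with `true_label` and `pred_label` columns.
#' @param labels optional character vector fixing the class set and order.
#' @return a `k x k` integer matrix of class `confusionMatrix` with
#'   dimnames `true` x `pred`.
#' @export
confusion <- function(records, labels = NULL) {
  stopifnot(is.data.frame(records))
  if (!all(c("true_label", "pred_label") %in% names(records)))
    stop("records need true_label and pred_label columns", call. = FALSE)
  seen <- unique(c(records$true_label, records$pred_label))
  if (is.null(labels)) {
    labels <- if (length(seen) > 0L && all(seen %in% lc1Classes()))
      intersect(lc1Classes(), seen)
    else sort(seen)
    if (length(labels) == 0L) labels <- lc1Classes()
  } else {
    unknown <- setdiff(seen, labels)
    if (length(unknown) > 0L)
      stop("unknown label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  tt <- table(true = factor(records$true_label, levels = labels),
              pred = factor(records$pred_label, levels = labels))
  cm <- unclass(as.matrix(tt))
  storage.mode(cm) <- "integer"
  names(dimnames(cm)) <- NULL
  class(cm) <- c("confusionMatrix", class(cm))
  cm
}

#' @export
print.confusionMatrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (%d classes, %d records)\n",
              nrow(x), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Evaluate a confusion matrix
#'
#' Computes overall accuracy (trace over total), per-class producer
#' accuracy (PA, recall), user accuracy (UA, precision) and F1, and the
#' macro-F1 as the unweighted mean of per-class F1.  Classes absent from
#' both truth and prediction are excluded from the macro mean; a class
#' with PA + UA = 0 contributes F1 = 0.
#'
#' @param cm a `confusionMatrix` (or plain square matrix with dimnames).
#' @return object of class `evalReport`: list with `oa`, `macro_f1`, `n`
#'   and a `classes` data frame (`label`, `pa`, `ua`, `f1`, `support`).
#' @examples
#' cm <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE,
#'              dimnames = list(c("A", "B"), c("A", "B")))
#' evaluate(cm)
#' @export
evaluate <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop("cm must be a square matrix", call. = FALSE)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  present <- rs > 0 | cs > 0
  d <- diag(as.matrix(cm))
  pa <- ifelse(rs > 0, d / rs, 0)
  ua <- ifelse(cs > 0, d / cs, 0)
  f1 <- ifelse(pa + ua > 0, 2 * pa * ua / (pa + ua), 0)
  classes <- data.frame(
    label = rownames(cm),
    pa = pa, ua = ua, f1 = f1,
    support = as.integer(rs),
    row.names = NULL, stringsAsFactors = FALSE
  )[present, , drop = FALSE]
  out <- list(
    oa = sum(d) / total,
    macro_f1 = mean(classes$f1),
    n = as.integer(total),
    classes = classes
  )
  class(out) <- "evalReport"
  out
}

#' @export
print.evalReport <- function(x, digits = 4, ...) {
  cat(sprintf("Evaluation over %d records, %d classes\n",
              x$n, nrow(x$classes)))
  cat(sprintf("  OA       %.4f\n  macro-F1 %.4f\n", x$oa, x$macro_f1))
  cls <- x$classes
  # PA/UA shown x100 with one decimal, as in crop-map accuracy tables
  cls$pa <- sprintf("%.1f", 100 * cls$pa)
  cls$ua <- sprintf("%.1f", 100 * cls$ua)
  cls$f1 <- sprintf("%.*f", digits, cls$f1)
  print(cls, row.names = FALSE)
  invisible(x)
}

#' Merge confusion-matrix classes into groups
#'
#' Sums rows and columns by group (e.g. the five cereal classes into one
#' CEREAL class); the record total is preserved.  Group order follows the
#' first appearance of each group along the original label order.
#'
#' @param cm a `confusionMatrix`.
#' @param group_map named character vector mapping every label of `cm` to
#'   its group label.
#' @return a grouped `confusionMatrix`.
#' @examples
#' cerealGroupMap()  # B11..B15 -> CEREAL, others unchanged
#' @export
groupClasses <- function(cm, group_map) {
  labels <- rownames(cm)
  miss <- setdiff(labels, names(group_map))
  if (length(miss) > 0L)
    stop("group_map is missing label(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  groups <- unname(group_map[labels])
  glev <- unique(groups)
  G <- matrix(0L, length(glev), length(labels),
              dimnames = list(glev, labels))
  G[cbind(match(groups, glev), seq_along(labels))] <- 1L
  out <- G %*% unclass(cm) %*% t(G)
  storage.mode(out) <- "integer"
  dimnames(out) <- list(glev, glev)
  class(out) <- c("confusionMatrix", class(out))
  out
}

#' Default cereal grouping map
#'
#' Maps B11--B15 to `CEREAL` and leaves the remaining LC1 classes as
#' singleton groups.
#'
#' @return named character vector over the 12 LC1 codes.
#' @export
cerealGroupMap <- function() {
  labels <- lc1Classes()
  setNames(ifelse(labels %in% cerealClasses(), "CEREAL", labels), labels)
}

#' Per-condition accuracy report for unfavorable photo conditions
#'
#' Tallies true/false classifications and overall accuracy per condition
#' tag (Blurry, Close, Early, Landscape, Object, Post-harvest), and
#' summarises the top-1 probability (MP) per condition alongside any
#' supplied reference record sets.
#'
#' @param records scored record table with a `condition` column.
#' @param references optional named list of scored record tables used as
#'   comparison sets for the top-1 probability summary.
#' @return object of class `conditionReport`: list with `conditions`
#'   (condition, false, true, oa -- OA rounded half-up to 2 decimals),
#'   `total` and `top1_summary` (quartiles of MP per condition/reference).
#' @export
conditionReport <- function(records, references = list()) {
  assertScored(records)
  if (!"condition" %in% names(records))
    stop("records need a condition column", call. = FALSE)
  labs <- conditionLabels()
  unknown <- setdiff(unique(records$condition), labs)
  if (length(unknown) > 0L)
    stop("unknown condition tag(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  correct <- records$pred_label == records$true_label
  cond <- factor(records$condition, levels = labs)
  true_n <- as.integer(tapply(correct, cond, sum, default = 0L))
  false_n <- as.integer(tapply(!correct, cond, sum, default = 0L))
  oa <- ifelse(true_n + false_n > 0,
               roundHalfUp(true_n / (true_n + false_n), 2), NA_real_)
  conditions <- data.frame(condition = labs, false = false_n,
                           true = true_n, oa = oa,
                           stringsAsFactors = FALSE)
  qs <- function(x) quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  top1 <- lapply(split(records$mp, cond), function(x)
    if (length(x) > 0) qs(x) else rep(NA_real_, 5))
  for (nm in names(references)) {
    assertScored(references[[nm]])
    top1[[nm]] <- qs(references[[nm]]$mp)
  }
  top1_summary <- data.frame(
    set = names(top1),
    do.call(rbind, top1),
    row.names = NULL, stringsAsFactors = FALSE
  )
  names(top1_summary)[-1] <- c("min", "q25", "median", "q75", "max")
  out <- list(conditions = conditions,
              total = nrow(records),
              top1_summary = top1_summary)
  class(out) <- "conditionReport"
  out
}

#' @export
print.conditionReport <- function(x, ...) {
  cat(sprintf("Unfavorable-condition report (%d records)\n", x$total))
  print(x$conditions, row.names = FALSE)
  invisible(x)
}

#' Country-by-class photo tally with marginals
#'
#' @param photos photo record table with `country` and `lc1` columns.
#' @return object of class `tallyTable`: integer matrix country x class
#'   with a `Total` row and column; the grand total sits in the corner.
#' @export
tallyTable <- function(photos) {
  stopifnot(is.data.frame(photos))
  if (nrow(photos) == 0L) {
    out <- matrix(0L, 1L, 1L, dimnames = list("Total", "Total"))
    class(out) <- c("tallyTable", class(out))
    return(out)
  }
  classes <- if (all(photos$lc1 %in% lc1Classes()))
    intersect(lc1Classes(), unique(photos$lc1)) else sort(unique(photos$lc1))
  tt <- table(country = factor(photos$country),
              class = factor(photos$lc1, levels = classes))
  m <- unclass(as.matrix(tt))
  m <- rbind(m, Total = colSums(m))
  m <- cbind(m, Total = rowSums(m))
  storage.mode(m) <- "integer"
  class(m) <- c("tallyTable", class(m))
  m
}

#' Grand total of a tally table
#'
#' @param tally a `tallyTable`.
#' @return integer record count.
#' @export
grandTotal <- function(tally) {
  as.integer(tally["Total", "Total"])
}

#' Regression of classification accuracy on image resolution
#'
#' Groups records by their native `(width, height)` pair, computes the
#' proportion of correct classifications per resolution bin, and fits an
#' ordinary least-squares line of that proportion against the bin's pixel
#' count (`width * height`).  A value near zero indicates accuracy is
#' unrelated to native resolution.
#'
#' @param records record table with `width`, `height` and either a
#'   `correct` column or `true_label`/`pred_label`.
#' @return list with `r_squared`, the fitted `slope`/`intercept` and the
#'   per-bin data frame (`width`, `height`, `pixels`, `n`, `prop_correct`).
#' @export
resolutionAccuracy <- function(records) {
  stopifnot(is.data.frame(records))
  if (!"correct" %in% names(records)) {
    assertScored(records)
    records$correct <- records$pred_label == records$true_label
  }
  key <- paste(records$width, records$height, sep = "x")
  if (length(unique(key)) < 2L)
    stop("need at least two distinct resolution bins", call. = FALSE)
  bins <- aggregate(records$correct, by = list(key = key), FUN = mean)
  n <- aggregate(records$correct, by = list(key = key), FUN = length)
  wh <- do.call(rbind, strsplit(bins$key, "x"))
  out <- data.frame(
    width = as.numeric(wh[, 1]),
    height = as.numeric(wh[, 2]),
    n = n$x,
    prop_correct = bins$x
  )
  out$pixels <- out$width * out$height
  fit <- lm(prop_correct ~ pixels, data = out)
  tss <- sum((out$prop_correct - mean(out$prop_correct))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(fit$residuals^2) / tss
  list(
    r_squared = r2,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    bins = out[order(out$pixels), c("width", "height", "pixels", "n",
                                    "prop_correct")]
  )
}
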