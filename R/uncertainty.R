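# Information-theoretic scoring of softmax vectors.
#
# Self-information and entropy are reported in bits (log base 2).  The
# expected information divergence and the equivalent reference probability
# (ERP) use the natural log so that the exponential in the ERP mapping
# inverts it; ERP itself is base-invariant as long as the same base is used
# in both steps.

.PROB_SUM_TOL <- 1e-9
.LOG_CLAMP <- 1e-15

#' Validate a probability vector
#'
#' Checks that `p` is a numeric vector of at least two non-negative entries
#' summing to one within tolerance.
#'
#' @param p numeric vector of class probabilities.
#' @param tol tolerance on `sum(p) - 1`.
#' @return `p`, invisibly; errors otherwise.
#' @export
validateProbVector <- function(p, tol = .PROB_SUM_TOL) {
  if (!is.numeric(p) || length(p) < 2L)
    stop("probability vector must be numeric with k >= 2 entries", call. = FALSE)
  if (anyNA(p))
    stop("probability vector contains NA", call. = FALSE)
  if (any(p < 0))
    stop("probability vector has negative entries", call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("probabilities sum to %.12f, not 1 (tol %g)", sum(p), tol),
         call. = FALSE)
  invisible(p)
}

#' Self-information of an event (bits)
#'
#' The surprise carried by an event of probability `p`: rare events carry
#' more information, a certain event carries none.
#'
#' @param p probability (or vector of probabilities) in (0, 1].
#' @return \eqn{-\log_2 p}, in bits.
#' @examples
#' selfInformation(0.5)   # 1 bit
#' selfInformation(0.25)  # 2 bits
#' @export
selfInformation <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p must lie in (0, 1]", call. = FALSE)
  -log2(p)
}

#' Shannon entropy of a probability vector (bits)
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} with the convention
#' \eqn{0 \log 0 = 0}.  Low entropy means the winning class stands out from
#' the rest of the distribution.
#'
#' @param p a valid probability vector (see [validateProbVector()]).
#' @return entropy in bits, in \eqn{[0, \log_2 k]}.
#' @examples
#' shannonEntropy(rep(1 / 4, 4))  # 2 bits
#' shannonEntropy(c(0.7, 0.2, 0.1))
#' @export
shannonEntropy <- function(p) {
  validateProbVector(p)
  pos <- p > 0
  -sum(p[pos] * log2(p[pos]))
}

#' Expected information divergence from the reference (winning) class
#'
#' The expected difference of information between the most probable class
#' \eqn{i^*} (ties broken by lowest index) and the remaining classes,
#' \deqn{E[D] = \log p_{i^*} - \frac{1}{1 - p_{i^*}}
#'   \sum_{i \ne i^*} p_i \log p_i ,}
#' using natural logarithms.  Entries below `1e-15` contribute zero to the
#' sum.  When \eqn{p_{i^*} = 1} the analytic limit is \eqn{+\infty} and
#' `Inf` is returned.
#'
#' @inheritParams shannonEntropy
#' @return a non-negative real, possibly `Inf`.
#' @examples
#' expectedDivergence(rep(1 / 3, 3))  # 0: symmetry
#' expectedDivergence(c(0.7, 0.2, 0.1))
#' @export
expectedDivergence <- function(p) {
  validateProbVector(p)
  istar <- which.max(p)
  pstar <- p[istar]
  if (pstar >= 1) return(Inf)
  rest <- p[-istar]
  keep <- rest > .LOG_CLAMP
  log(pstar) - sum(rest[keep] * log(rest[keep])) / (1 - pstar)
}

#' Equivalent reference probability (ERP)
#'
#' Maps the unbounded expected divergence onto \eqn{[0, 1]}:
#' \deqn{p^* = \frac{e^{E[D]}}{e^{E[D]} + k - 1}.}
#' Values near 1 mean very high confidence in the most probable class with
#' the remaining mass spread as evenly as possible over the other classes;
#' a uniform vector maps to \eqn{1/k} and a one-hot vector to 1.
#'
#' @inheritParams shannonEntropy
#' @return ERP in \eqn{[0, 1]}.
#' @examples
#' erp(rep(1 / 12, 12))  # 1/12
#' erp(c(0.7, 0.2, 0.1))
#' @export
erp <- function(p) {
  validateProbVector(p)
  k <- length(p)
  if (k < 2L) stop("ERP requires k >= 2 classes", call. = FALSE)
  d <- expectedDivergence(p)
  if (is.infinite(d)) return(1)
  # 1 / (1 + (k-1) e^{-D}) is the overflow-safe form of e^D / (e^D + k - 1)
  1 / (1 + (k - 1) * exp(-d))
}

# Column names holding class probabilities ("p_<label>"), in table order.
probColumns <- function(records) {
  cols <- grep("^p_", names(records), value = TRUE)
  if (length(cols) < 2L)
    stop("records need at least two probability columns named 'p_<label>'",
         call. = FALSE)
  cols
}

#' Class labels encoded in a record table's probability columns
#'
#' @param records a classification record table with `p_<label>` columns.
#' @return character vector of class labels in column order.
#' @export
recordLabels <- function(records) {
  sub("^p_", "", probColumns(records))
}

#' Score classification records with uncertainty metrics
#'
#' Attaches, per record, the predicted label (argmax of the softmax vector,
#' ties to the lowest class index), the maximum probability (MP), the
#' Shannon entropy in bits, the expected information divergence and the
#' equivalent reference probability (ERP), plus a logical `correct` column.
#'
#' @param records data frame with columns `id`, `true_label` and one
#'   `p_<label>` column per class.
#' @return `records` with columns `pred_label`, `correct`, `mp`, `entropy`,
#'   `divergence`, `erp` appended; row order preserved.
#' @examples
#' r <- genRecords(counts = c(A = 5, B = 5), seed = 1)
#' head(scoreRecords(r))
#' @export
scoreRecords <- function(records) {
  stopifnot(is.data.frame(records))
  cols <- probColumns(records)
  labels <- sub("^p_", "", cols)
  k <- length(cols)
  if (nrow(records) == 0L) {
    records$pred_label <- character(0)
    records$correct <- logical(0)
    records$mp <- records$entropy <- records$divergence <- records$erp <- numeric(0)
    return(records)
  }
  P <- as.matrix(records[cols])
  bad <- which(rowSums(is.na(P)) > 0 | rowSums(P < 0) > 0 |
                 abs(rowSums(P) - 1) > .PROB_SUM_TOL)
  if (length(bad) > 0L) {
    id <- if ("id" %in% names(records)) records$id[bad[1L]] else bad[1L]
    stop(sprintf("invalid probability vector for record '%s'", id), call. = FALSE)
  }
  n <- nrow(P)
  istar <- max.col(P, ties.method = "first")
  pstar <- P[cbind(seq_len(n), istar)]

  L2 <- P * log2(P)
  L2[P <= 0] <- 0
  entropy <- -rowSums(L2)

  Ln <- P * log(P)
  Ln[P <= .LOG_CLAMP] <- 0
  pstar_term <- ifelse(pstar > .LOG_CLAMP, pstar * log(pstar), 0)
  restsum <- rowSums(Ln) - pstar_term
  div <- ifelse(pstar >= 1, Inf, log(pstar) - restsum / (1 - pstar))
  erpv <- ifelse(is.infinite(div), 1, 1 / (1 + (k - 1) * exp(-div)))

  records$pred_label <- labels[istar]
  if ("true_label" %in% names(records))
    records$correct <- records$pred_label == records$true_label
  records$mp <- pstar
  records$entropy <- entropy
  records$divergence <- div
  records$erp <- erpv
  records
}
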