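# Independent brute-force oracles used to cross-check the package's
# implementations.  Each is written along a different computational path
# than the function it checks.

# Divergence oracle: the expected divergence is the p-weighted average of
# the pairwise information differences log(p*) - log(p_i) over the losing
# classes (weights p_i / (1 - p*)), summed term by term.
oracleDivergence <- function(p) {
  istar <- which.max(p)
  pstar <- p[istar]
  if (pstar >= 1) return(Inf)
  acc <- 0
  for (i in seq_along(p)) {
    if (i == istar || p[i] <= 1e-15) next
    w <- p[i] / (1 - pstar)
    acc <- acc + w * (log(pstar) - log(p[i]))
  }
  acc
}

oracleErp <- function(p) {
  d <- oracleDivergence(p)
  if (is.infinite(d)) return(1)
  exp(d) / (exp(d) + length(p) - 1)
}

oracleEntropy <- function(p) {
  acc <- 0
  for (x in p) if (x > 0) acc <- acc - x * log2(x)
  acc
}

# Exhaustive threshold-search oracle: walk the grid from the top and
# return the first value whose correct-loss stays within budget.
oracleThreshold <- function(correct_vals, loss_frac, step) {
  grid <- rev(round(seq(0, 1, by = step), 10))
  budget <- loss_frac * length(correct_vals)
  for (t in grid) {
    if (sum(correct_vals < t) <= budget) return(t)
  }
  0
}

# Greedy largest-remainder oracle: floor quotas, then hand out the
# remaining units one at a time to the largest outstanding remainder.
oracleApportion <- function(weights, total) {
  quota <- weights / sum(weights) * total
  alloc <- floor(quota)
  rem <- quota - alloc
  while (sum(alloc) < total) {
    i <- which.max(rem)
    alloc[i] <- alloc[i] + 1
    rem[i] <- -Inf
  }
  as.integer(alloc)
}

# Per-class PA/UA/F1 oracle computed record-by-record, no matrix algebra.
oracleClassMetrics <- function(true, pred, label) {
  tp <- sum(true == label & pred == label)
  pa <- if (sum(true == label) > 0) tp / sum(true == label) else 0
  ua <- if (sum(pred == label) > 0) tp / sum(pred == label) else 0
  f1 <- if (pa + ua > 0) 2 * pa * ua / (pa + ua) else 0
  c(pa = pa, ua = ua, f1 = f1)
}

randomSimplex <- function(k) {
  g <- rgamma(k, shape = runif(1, 0.3, 3))
  g / sum(g)
}

# Small scored fixture with metric values chosen by hand.
toyScored <- function(mp, erp, correct) {
  data.frame(
    id = sprintf("t%02d", seq_along(mp)),
    true_label = "A",
    pred_label = ifelse(correct, "A", "B"),
    mp = mp, erp = erp,
    stringsAsFactors = FALSE
  )
}
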