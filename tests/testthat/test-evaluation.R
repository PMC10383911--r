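# Confusion matrices, accuracy metrics, grouping, condition reports,
# tallies and the resolution regression.

twoClassToy <- function() {
  data.frame(
    true_label = c(rep("A", 10), rep("B", 10)),
    pred_label = c(rep("A", 8), rep("B", 2), "A", rep("B", 9)),
    stringsAsFactors = FALSE
  )
}

test_that("confusion tallies records into a fixed-order grid", {
  cm <- confusion(twoClassToy())
  expect_equal(unclass(cm)[, ], matrix(c(8L, 1L, 2L, 9L), 2,
               dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(sum(cm), 20)

  # permutation invariance
  set.seed(1)
  shuffled <- twoClassToy()[sample(20), ]
  expect_equal(confusion(shuffled), cm)

  # empty input: all-zero matrix
  empty <- confusion(data.frame(true_label = character(0),
                                pred_label = character(0)))
  expect_true(all(empty == 0L))

  # LC1 labels take canonical order
  r <- data.frame(true_label = c("B55", "B11"), pred_label = c("B55", "B11"))
  expect_equal(rownames(confusion(r)), c("B11", "B55"))

  expect_error(confusion(data.frame(true_label = "A", pred_label = "Z"),
                         labels = c("A", "B")), "Z")
})

test_that("evaluate reproduces hand-computed PA/UA/macro-F1", {
  rep_ <- evaluate(confusion(twoClassToy()))
  expect_equal(rep_$oa, 17 / 20)
  a <- rep_$classes[rep_$classes$label == "A", ]
  expect_equal(a$pa, 0.8)
  expect_equal(a$ua, 8 / 9, tolerance = 1e-12)
  expect_equal(rep_$macro_f1, 0.849624060150376, tolerance = 1e-12)

  perfect <- confusion(data.frame(true_label = c("A", "B", "C"),
                                  pred_label = c("A", "B", "C")))
  pr <- evaluate(perfect)
  expect_equal(pr$oa, 1.0)
  expect_equal(pr$macro_f1, 1.0)

  expect_error(evaluate(matrix(0, 2, 2)), "empty")
})

test_that("evaluate agrees with a per-class brute-force oracle on random matrices", {
  set.seed(303)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    labels <- paste0("c", seq_len(k))
    n <- sample(20:200, 1)
    true <- sample(labels, n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, true, sample(labels, n, replace = TRUE))
    rep_ <- evaluate(confusion(data.frame(true_label = true,
                                          pred_label = pred),
                               labels = labels))
    f1s <- numeric(0)
    for (lab in labels) {
      if (!lab %in% c(true, pred)) next
      m <- oracleClassMetrics(true, pred, lab)
      row <- rep_$classes[rep_$classes$label == lab, ]
      expect_equal(row$pa, unname(m["pa"]), tolerance = 1e-12)
      expect_equal(row$ua, unname(m["ua"]), tolerance = 1e-12)
      f1s <- c(f1s, unname(m["f1"]))
    }
    expect_equal(rep_$macro_f1, mean(f1s), tolerance = 1e-12)
    expect_equal(rep_$oa, mean(true == pred), tolerance = 1e-12)
  }
})

test_that("macro-F1 is invariant to class relabelling", {
  set.seed(4)
  labels <- paste0("c", 1:5)
  true <- sample(labels, 150, replace = TRUE)
  pred <- ifelse(runif(150) < 0.7, true, sample(labels, 150, replace = TRUE))
  base <- evaluate(confusion(data.frame(true_label = true, pred_label = pred)))
  perm <- setNames(rev(labels), labels)
  swapped <- evaluate(confusion(data.frame(true_label = unname(perm[true]),
                                           pred_label = unname(perm[pred]))))
  expect_equal(swapped$macro_f1, base$macro_f1, tolerance = 1e-12)
  expect_equal(swapped$oa, base$oa, tolerance = 1e-12)
})

test_that("class grouping preserves totals and never lowers OA for confusable groups", {
  r <- scoreRecords(genRecords(seed = 31))
  cm <- confusion(r)
  expect_equal(groupClasses(cm, setNames(lc1Classes(), lc1Classes())), cm)

  g <- groupClasses(cm, cerealGroupMap())
  expect_equal(dim(g), c(8, 8))
  expect_equal(sum(g), sum(cm))
  expect_gte(evaluate(g)$oa, evaluate(cm)$oa)

  expect_error(groupClasses(cm, cerealGroupMap()[-1]), "B11")
})

test_that("condition report reproduces counts, OA rounding and quartile summaries", {
  counts <- lucasConditionCounts()
  rows <- list()
  set.seed(8)
  for (i in seq_len(nrow(counts))) {
    n_true <- counts$true[i]; n_false <- counts$false[i]
    rows[[i]] <- data.frame(
      true_label = "B11",
      pred_label = c(rep("B11", n_true), rep("B13", n_false)),
      condition = counts$condition[i],
      mp = runif(n_true + n_false, 0.2, 0.9),
      erp = runif(n_true + n_false),
      stringsAsFactors = FALSE
    )
  }
  tagged <- do.call(rbind, rows)
  rep_ <- conditionReport(tagged)
  expect_equal(rep_$conditions$oa,
               c(0.54, 0.54, 0.31, 0.41, 0.37, 0.20))
  expect_equal(rep_$total, 354)
  expect_equal(rep_$conditions$true + rep_$conditions$false, rep(59L, 6))

  # all-correct fixture
  ok <- tagged
  ok$pred_label <- ok$true_label
  expect_true(all(conditionReport(ok)$conditions$oa == 1))

  # reference sets appear in the top-1 summary
  ref <- scoreRecords(genRecords(counts = c(B11 = 40, B13 = 40), seed = 2))
  rep2 <- conditionReport(tagged, references = list(balanced = ref))
  expect_true("balanced" %in% rep2$top1_summary$set)
  expect_equal(rep2$top1_summary[rep2$top1_summary$set == "balanced",
                                 "median"],
               unname(quantile(ref$mp, 0.5)))

  bad <- tagged
  bad$condition[1] <- "Rainy"
  expect_error(conditionReport(bad), "Rainy")
})

test_that("tallyTable produces marginals that add up", {
  photos <- data.frame(
    country = c("AT", "AT", "BE", "BE", "BE"),
    lc1 = c("B11", "B12", "B11", "B11", "B55")
  )
  tt <- tallyTable(photos)
  expect_equal(grandTotal(tt), 5L)
  expect_equal(tt["AT", "Total"], 2L)
  expect_equal(tt["Total", "B11"], 3L)
  expect_equal(grandTotal(tallyTable(photos[0, ])), 0L)
})

test_that("resolution-accuracy regression behaves at its analytic extremes", {
  # two bins: a line through two points fits exactly
  r2 <- data.frame(width = c(rep(640, 50), rep(1600, 50)),
                   height = c(rep(480, 50), rep(1200, 50)),
                   correct = c(runif(50) < 0.5, runif(50) < 0.8))
  expect_equal(resolutionAccuracy(r2)$r_squared, 1.0, tolerance = 1e-12)

  # proportion exactly linear in pixel count: equally spaced pixel counts
  # with correct-counts 10/20/30/40 out of 50 give a perfect line
  widths <- c(800, 1600, 2400, 3200)
  n_correct <- c(10, 20, 30, 40)
  rows <- lapply(seq_along(widths), function(i) {
    data.frame(width = widths[i], height = 600,
               correct = rep(c(TRUE, FALSE), c(n_correct[i], 50 - n_correct[i])))
  })
  ra <- resolutionAccuracy(do.call(rbind, rows))
  expect_equal(ra$r_squared, 1.0, tolerance = 1e-10)
  expect_equal(ra$bins$prop_correct, c(0.2, 0.4, 0.6, 0.8))

  # independence: R^2 near zero over many resolution bins on a seeded draw
  set.seed(55)
  widths <- seq(640, 4672, length.out = 60)
  idx <- sample(60, 6000, replace = TRUE)
  ind <- data.frame(width = widths[idx], height = round(widths[idx] * 0.75),
                    correct = runif(6000) < 0.75)
  expect_lt(resolutionAccuracy(ind)$r_squared, 0.05)

  expect_error(resolutionAccuracy(data.frame(width = 1, height = 1,
                                             correct = TRUE)), "two distinct")
})
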