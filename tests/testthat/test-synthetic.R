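# The synthetic-data generator: record structure, parameter recovery,
# confusion-kernel behavior, photo tables, images.

test_that("default generator configuration is internally consistent", {
  counts <- defaultClassCounts()
  expect_equal(sum(counts), 15876L)
  acc <- defaultClassAccuracies()
  expect_true(all(acc >= 0 & acc <= 1))
  K <- defaultConfusionKernel()
  expect_equal(unname(rowSums(K)), rep(1, 12), tolerance = 1e-12)
  expect_true(all(diag(K) == 0))
  # cereal block: most error mass of a cereal goes to cereals + grassland
  expect_gt(sum(K["B11", c("B12", "B13", "B14", "B15", "B55")]), 0.8)
  expect_gt(sum(K["B55", cerealClasses()]), 0.6)
})

test_that("generated records have valid vectors, argmax predictions and exact accuracy at the extremes", {
  r <- genRecords(counts = c(A = 30, B = 30, C = 30),
                  accuracy = c(A = 1, B = 1, C = 1), seed = 2)
  expect_true(all(r$correct))
  P <- as.matrix(r[paste0("p_", c("A", "B", "C"))])
  expect_equal(unname(rowSums(P)), rep(1, 90), tolerance = 1e-12)
  expect_equal(r$pred_label, c("A", "B", "C")[max.col(P, "first")])
  for (i in sample(90, 10)) validateProbVector(P[i, ])
  # determinism
  expect_identical(r, genRecords(counts = c(A = 30, B = 30, C = 30),
                                 accuracy = c(A = 1, B = 1, C = 1), seed = 2))
})

test_that("empirical accuracy tracks the configured rate within binomial error", {
  n <- 10000
  r <- genRecords(counts = c(A = n, B = 200), accuracy = c(A = 0.8, B = 0.8),
                  seed = 8)
  emp <- mean(r$correct[r$true_label == "A"])
  expect_lt(abs(emp - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("error destinations follow the confusion kernel", {
  counts <- c(B11 = 4000, B12 = 100, B13 = 100, B14 = 100, B15 = 100,
              B55 = 100)
  K <- defaultConfusionKernel(names(counts))
  r <- genRecords(counts = counts, accuracy = setNames(rep(0.5, 6),
                                                       names(counts)),
                  kernel = K, seed = 12)
  err <- r[r$true_label == "B11" & !r$correct, ]
  emp <- table(factor(err$pred_label, levels = names(counts)))
  emp <- as.numeric(emp / sum(emp))
  expected <- as.numeric(K["B11", ])
  n_err <- nrow(err)
  for (j in seq_along(expected)) {
    se <- sqrt(max(expected[j] * (1 - expected[j]), 1e-9) / n_err)
    expect_lt(abs(emp[j] - expected[j]), max(3 * se, 0.02))
  }
})

test_that("per-class producer accuracy recovers the configured accuracies (3 SD at n = 5000)", {
  labels <- lc1Classes()
  n <- 5000L
  acc <- defaultClassAccuracies()
  r <- genRecords(counts = setNames(rep(n, 12), labels), accuracy = acc,
                  seed = 99)
  rep_ <- evaluate(confusion(scoreRecords(r)))
  for (lab in labels) {
    pa <- rep_$classes$pa[rep_$classes$label == lab]
    expect_lt(abs(pa - acc[[lab]]),
              3 * sqrt(acc[[lab]] * (1 - acc[[lab]]) / n) + 1e-9)
  }
})

test_that("correct records score stochastically higher ERP than incorrect ones", {
  r <- scoreRecords(genRecords(seed = 42))
  w <- wilcox.test(r$erp[r$correct], r$erp[!r$correct],
                   alternative = "greater")
  expect_lt(w$p.value, 1e-10)
  # bimodal MP marginals: the two groups peak on opposite sides of 0.5
  expect_gt(median(r$mp[r$correct]), 0.6)
  expect_lt(median(r$mp[!r$correct]), 0.5)
})

test_that("photo tables honour their counts, window placement and resolution mix", {
  counts <- data.frame(country = c("AT", "FR"), B11 = c(30L, 50L),
                       B16 = c(20L, 40L))
  p <- genPhotoTable(counts = counts, seed = 4)
  expect_equal(nrow(p), 140)
  expect_equal(sum(p$country == "FR" & p$lc1 == "B11"), 50)
  expect_true(all(p$quality == "clean"))

  windows <- data.frame(country = rep(c("AT", "FR"), each = 2),
                        crop = rep(c("B11", "B16"), 2),
                        start_hm = c(9L, 11L, 9L, 11L),
                        end_hm = c(15L, 19L, 15L, 19L))
  p1 <- genPhotoTable(counts = counts, windows = windows,
                      in_window_frac = 1, seed = 5)
  expect_equal(nrow(selectMature(p1, windows)), nrow(p1))

  n <- 1000L
  p04 <- genPhotoTable(counts = data.frame(country = "AT", B11 = n),
                       windows = windows[1, ], in_window_frac = 0.4,
                       seed = 6)
  kept <- nrow(selectMature(p04, windows[1, ]))
  expect_lt(abs(kept - 0.4 * n), 3 * sqrt(0.4 * 0.6 * n))

  # resolution mix dominated by the configured main mode
  frac1600 <- mean(p$width == 1600 & p$height == 1200)
  expect_gt(frac1600, 0.5)
})

test_that("scaled default photo table mirrors the published tally shape", {
  p <- genPhotoTable(scale = 0.05, seed = 20)
  tab <- lucasTable1()
  cls <- intersect(lc1Classes(), names(tab))
  expect_equal(nrow(p), sum(ceiling(tab[cls] * 0.05)))
  expect_equal(sort(unique(p$country)), sort(tab$country))
})

test_that("generated images separate configured classes and are reproducible", {
  img <- genImages(labels = c("A", "B"), n_per_class = 30, seed = 14)
  expect_length(img$x, 60)
  expect_true(all(vapply(img$x, function(m) all(m >= 0 & m <= 1),
                         logical(1))))
  expect_identical(img, genImages(labels = c("A", "B"), n_per_class = 30,
                                  seed = 14))

  # maximally separated classes: nearest-mean classifier is near perfect
  test <- genImages(labels = c("A", "B"), n_per_class = 30, seed = 15)
  mu <- vapply(split(img$x, img$y), function(xs)
    mean(vapply(xs, mean, numeric(1))), numeric(1))
  pred <- names(mu)[apply(abs(outer(vapply(test$x, mean, numeric(1)),
                                    mu, "-")), 1, which.min)]
  expect_gt(mean(pred == test$y), 0.95)

  # identical class parameters: chance-level accuracy
  same <- data.frame(mu = c(0.5, 0.5), freq = c(1, 1), amp = c(0.15, 0.15))
  img0 <- genImages(labels = c("A", "B"), n_per_class = 100,
                    class_params = same, seed = 16)
  test0 <- genImages(labels = c("A", "B"), n_per_class = 100,
                     class_params = same, seed = 17)
  mu0 <- vapply(split(img0$x, img0$y), function(xs)
    mean(vapply(xs, mean, numeric(1))), numeric(1))
  pred0 <- names(mu0)[apply(abs(outer(vapply(test0$x, mean, numeric(1)),
                                      mu0, "-")), 1, which.min)]
  expect_lt(abs(mean(pred0 == test0$y) - 0.5), 3 * sqrt(0.25 / 200))
})
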