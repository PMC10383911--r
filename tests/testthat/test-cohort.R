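# Maturity filtering, stratified sampling, cohort construction.

smallPhotoFixture <- function(seed = 3) {
  counts <- data.frame(
    country = c("AT", "DE", "FR"),
    A = c(120L, 300L, 180L),
    B = c(200L, 150L, 250L)
  )
  genPhotoTable(counts = counts, seed = seed)
}

test_that("largest-remainder apportionment matches the greedy oracle and stays within one", {
  set.seed(404)
  for (i in 1:100) {
    m <- sample(2:10, 1)
    w <- sample(1:500, m)
    total <- sample(1:sum(w), 1)
    alloc <- largestRemainder(w, total)
    expect_equal(alloc, oracleApportion(w, total))
    expect_equal(sum(alloc), total)
    expect_true(all(abs(alloc - w / sum(w) * total) < 1))
  }
})

test_that("capped apportionment respects caps and falls back to capacity", {
  a <- cropvision:::allocWithCaps(c(80, 15, 5), 85, caps = c(70, 20, 10))
  expect_equal(sum(a), 85)
  expect_true(all(a <= c(70, 20, 10)))
  # zero-weight stratum receives units only when the others saturate
  b <- cropvision:::allocWithCaps(c(10, 0), 12, caps = c(10, 5))
  expect_equal(b, c(10L, 2L))
})

test_that("selectMature keeps exactly the in-window photos and counts the drops", {
  windows <- data.frame(country = "XX", crop = "A",
                        start_hm = 9L, end_hm = 15L)
  photos <- data.frame(
    id = sprintf("p%02d", 1:100),
    country = "XX",
    lc1 = c(rep("A", 80), rep("B", 20)),
    # 40 of the class-A photos inside the window, 40 outside
    date = c(rep(as.Date("2018-06-01"), 40),
             rep(as.Date("2018-11-01"), 40),
             rep(as.Date("2018-06-01"), 20))
  )
  kept <- selectMature(photos, windows)
  expect_equal(nrow(kept), 40)
  expect_true(all(kept$lc1 == "A"))
  expect_equal(attr(kept, "dropped_no_window"), 20)
  expect_equal(attr(kept, "dropped_out_of_window"), 40)
})

test_that("training sample is stratified by availability and deterministic", {
  photos <- smallPhotoFixture()
  ids <- trainingSample(photos, n_per_class = 100L, seed = 42)
  expect_equal(length(ids), 200)
  expect_identical(ids, trainingSample(photos, n_per_class = 100L, seed = 42))
  sel <- photos[photos$id %in% ids, ]
  # per-country allocation within each class matches the apportionment oracle
  for (cls in c("A", "B")) {
    avail <- table(photos$country[photos$lc1 == cls])
    got <- table(factor(sel$country[sel$lc1 == cls],
                        levels = names(avail)))
    expect_equal(as.integer(got), oracleApportion(as.numeric(avail), 100))
  }
  # class with exactly n photos: all selected
  exact <- photos[photos$lc1 == "A", ][1:100, ]
  expect_setequal(trainingSample(exact, n_per_class = 100L, seed = 1), exact$id)
  expect_error(trainingSample(photos, n_per_class = 10000L, seed = 1),
               "only")
})

test_that("balanced set mirrors training geography within rounding", {
  photos <- smallPhotoFixture()
  train_ids <- trainingSample(photos, n_per_class = 100L, seed = 42)
  training <- photos[photos$id %in% train_ids, ]
  leftover <- photos[!photos$id %in% train_ids, ]
  bal <- balancedSet(leftover, training, n_per_class = 40L, seed = 43)
  expect_equal(length(bal), 80)
  expect_true(all(bal %in% leftover$id))
  sel <- leftover[leftover$id %in% bal, ]
  for (cls in c("A", "B")) {
    ref <- table(training$country[training$lc1 == cls])
    got <- table(factor(sel$country[sel$lc1 == cls], levels = names(ref)))
    target <- oracleApportion(as.numeric(ref), 40)
    expect_true(all(abs(as.integer(got) - target) <= 1))
  }
  expect_error(balancedSet(leftover[1:10, ], training, n_per_class = 40L),
               "leftover")
})

test_that("imbalanced set caps per class while retaining the balanced members", {
  photos <- smallPhotoFixture()
  train_ids <- trainingSample(photos, n_per_class = 100L, seed = 42)
  training <- photos[photos$id %in% train_ids, ]
  leftover <- photos[!photos$id %in% train_ids, ]
  bal <- balancedSet(leftover, training, n_per_class = 40L, seed = 43)
  imb <- imbalancedSet(leftover, bal, cap = 150L, seed = 44)
  sel <- leftover[leftover$id %in% imb, ]
  cnt <- table(sel$lc1)
  left_cnt <- table(leftover$lc1)
  expect_equal(as.integer(cnt), pmin(as.integer(left_cnt), 150L))
  expect_true(all(bal %in% imb))
  # uncapped class is taken whole
  expect_equal(sum(sel$lc1 == "A"), min(sum(leftover$lc1 == "A"), 150L))
})

test_that("condition sample takes at most one photo per (year, class, condition) cell", {
  full <- genPhotoTable(
    counts = data.frame(country = "AT", A = 5L),
    rejected_per_cell = 2L, seed = 6
  )
  rejected <- full[full$quality == "rejected", ]
  # one class x 5 years x 6 conditions, every cell doubly occupied
  ids <- conditionSample(rejected, seed = 10)
  expect_equal(length(ids), 30)
  expect_equal(nrow(attr(ids, "empty_cells")), 0)
  sel <- rejected[rejected$id %in% ids, ]
  expect_equal(anyDuplicated(paste(sel$year, sel$lc1, sel$condition)), 0L)

  # empty cells are skipped, not back-filled
  sparse <- rejected[rejected$condition != "Blurry", ]
  ids2 <- conditionSample(sparse, seed = 10)
  expect_equal(length(ids2), 25)
  expect_true(all(attr(ids2, "empty_cells")$condition == "Blurry"))
})

test_that("buildCohorts satisfies the disjointness and containment invariants", {
  photos <- smallPhotoFixture()
  co <- buildCohorts(photos, windows = NULL, n_train = 100L,
                     n_balanced = 40L, cap = 150L, seed = 7)
  expect_length(intersect(co$training, co$balanced), 0)
  expect_length(intersect(co$training, co$imbalanced), 0)
  expect_true(all(co$balanced %in% co$imbalanced))
  expect_equal(as.integer(table(photos$lc1[photos$id %in% co$balanced])),
               c(40L, 40L))
  # determinism end to end
  co2 <- buildCohorts(photos, windows = NULL, n_train = 100L,
                      n_balanced = 40L, cap = 150L, seed = 7)
  expect_identical(co$imbalanced, co2$imbalanced)
})
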