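# Construction of the study cohorts from a photo-metadata table:
# maturity filtering, the stratified per-class training sample, the
# balanced inference set, the capped imbalanced inference set, and the
# per-(year, class, condition) unfavorable-condition sample.

# Run code with a local, restored RNG state so cohort draws are
# reproducible without touching the caller's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# sample() that never unfolds a length-1 x into 1:x
resample <- function(x, size = length(x)) {
  x[sample.int(length(x), size)]
}

#' Largest-remainder apportionment
#'
#' Splits `total` units across strata proportionally to `weights`: each
#' stratum first gets the floor of its exact quota, then the remaining
#' units go to the strata with the largest fractional remainders (ties
#' broken by stratum order).  Every allocation differs from the exact
#' quota by less than one unit.
#'
#' @param weights non-negative numeric vector (availability or target
#'   proportions).
#' @param total integer number of units to allocate.
#' @return integer vector of allocations summing to `total`.
#' @export
largestRemainder <- function(weights, total) {
  stopifnot(all(weights >= 0), sum(weights) > 0, total >= 0)
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    frac <- quota - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# Largest-remainder allocation with per-stratum capacity caps: overflow
# is clipped and re-apportioned over the remaining open strata, so the
# result matches the target proportions as closely as availability
# permits.  Requires sum(caps) >= total.
allocWithCaps <- function(weights, total, caps) {
  stopifnot(length(weights) == length(caps), sum(caps) >= total)
  alloc <- integer(length(weights))
  open <- rep(TRUE, length(weights))
  remaining <- as.integer(total)
  repeat {
    idx <- which(open & weights > 0)
    if (remaining == 0L || length(idx) == 0L) break
    a <- largestRemainder(weights[idx], remaining)
    alloc[idx] <- alloc[idx] + a
    over <- alloc > caps
    if (!any(over)) {
      remaining <- 0L
      break
    }
    remaining <- as.integer(sum(alloc[over] - caps[over]))
    alloc[over] <- caps[over]
    open[over] <- FALSE
  }
  # weights exhausted (all open strata have zero weight): fill by capacity
  if (remaining > 0L) {
    for (i in order(-(caps - alloc))) {
      take <- min(remaining, caps[i] - alloc[i])
      alloc[i] <- alloc[i] + as.integer(take)
      remaining <- remaining - as.integer(take)
      if (remaining == 0L) break
    }
  }
  alloc
}

#' Keep photos taken inside their crop's maturity window
#'
#' Joins photos to maturity windows on (country, crop) and keeps those
#' whose survey date falls in the window.  Photos with no window for
#' their (country, crop) are dropped and counted.
#'
#' @param photos photo table with `country`, `lc1`, `date` columns.
#' @param windows maturity-window table (`country`, `crop`, `start_hm`,
#'   `end_hm`), e.g. from [deriveMaturityWindows()].
#' @return the in-window subset of `photos`, with attributes
#'   `dropped_no_window` and `dropped_out_of_window` (counts).
#' @export
selectMature <- function(photos, windows) {
  stopifnot(is.data.frame(photos), is.data.frame(windows))
  if (nrow(photos) == 0L) {
    attr(photos, "dropped_no_window") <- 0L
    attr(photos, "dropped_out_of_window") <- 0L
    return(photos)
  }
  wkey <- paste(windows$country, windows$crop)
  pkey <- paste(photos$country, photos$lc1)
  i <- match(pkey, wkey)
  has_window <- !is.na(i)
  hm <- dateToHalfMonth(photos$date)
  inside <- has_window &
    windowContains(windows$start_hm[i], windows$end_hm[i], hm)
  out <- photos[which(inside), , drop = FALSE]
  attr(out, "dropped_no_window") <- sum(!has_window)
  attr(out, "dropped_out_of_window") <- sum(has_window & !inside)
  out
}

# per-class, per-country stratified draw of `targets` photos (named by
# country); errors name the class/country on shortfall
drawStratified <- function(photos, class, targets) {
  picked <- character(0)
  for (ctry in names(targets)) {
    t_i <- targets[[ctry]]
    if (t_i == 0L) next
    ids <- photos$id[photos$country == ctry]
    if (length(ids) < t_i)
      stop(sprintf("class %s short in country %s: need %d, have %d",
                   class, ctry, t_i, length(ids)), call. = FALSE)
    picked <- c(picked, resample(ids, t_i))
  }
  picked
}

#' Stratified training sample
#'
#' Draws exactly `n_per_class` clean photos per class, allocated across
#' countries proportionally to availability with largest-remainder
#' rounding, and sampled uniformly within each (class, country) cell.
#' Deterministic given `seed`.
#'
#' @param photos photo table (`id`, `country`, `lc1`, `quality`).
#' @param n_per_class photos per class (default 400).
#' @param seed integer RNG seed.
#' @return character vector of selected photo ids.
#' @export
trainingSample <- function(photos, n_per_class = 400L, seed = 1L) {
  stopifnot(is.data.frame(photos))
  clean <- if ("quality" %in% names(photos))
    photos[photos$quality == "clean", , drop = FALSE] else photos
  withSeed(seed, {
    ids <- character(0)
    for (cls in sort(unique(clean$lc1))) {
      sub <- clean[clean$lc1 == cls, , drop = FALSE]
      if (nrow(sub) < n_per_class)
        stop(sprintf("class %s has only %d clean photos (< %d)",
                     cls, nrow(sub), n_per_class), call. = FALSE)
      avail <- table(sub$country)
      alloc <- largestRemainder(as.numeric(avail), n_per_class)
      names(alloc) <- names(avail)
      ids <- c(ids, drawStratified(sub, cls, as.list(alloc)))
    }
    ids
  })
}

#' Balanced inference set matching the training geography
#'
#' Draws `n_per_class` photos per class from the leftover pool with
#' per-country proportions matching those of the training sample for the
#' same class (largest-remainder rounding).  Where a country's leftover
#' pool cannot carry its proportional share -- unavoidable when a class's
#' leftover pool is barely larger than the set being drawn -- the excess
#' is re-apportioned over the remaining countries, keeping the geography
#' as close to the training sample as availability permits.  A class
#' whose whole pool is smaller than `n_per_class` is an error.
#'
#' @param leftover photo table disjoint from the training sample.
#' @param training photo table of the training sample (the geographic
#'   reference).
#' @param n_per_class photos per class (default 85, the size of the least
#'   represented class in the study setting).
#' @param seed integer RNG seed.
#' @return character vector of selected photo ids.
#' @export
balancedSet <- function(leftover, training, n_per_class = 85L, seed = 1L) {
  stopifnot(is.data.frame(leftover), is.data.frame(training))
  withSeed(seed, {
    ids <- character(0)
    for (cls in sort(unique(training$lc1))) {
      ref <- training[training$lc1 == cls, , drop = FALSE]
      pool <- leftover[leftover$lc1 == cls, , drop = FALSE]
      if (nrow(pool) < n_per_class)
        stop(sprintf("class %s has only %d leftover photos (< %d)",
                     cls, nrow(pool), n_per_class), call. = FALSE)
      countries <- sort(unique(c(ref$country, pool$country)))
      refc <- as.numeric(table(factor(ref$country, levels = countries)))
      avail <- as.numeric(table(factor(pool$country, levels = countries)))
      alloc <- allocWithCaps(refc, n_per_class, avail)
      names(alloc) <- countries
      ids <- c(ids, drawStratified(pool, cls, as.list(alloc)))
    }
    ids
  })
}

#' Capped imbalanced inference set
#'
#' Takes all leftover photos per class, capped at `cap`; when a class is
#' capped, the balanced-set members are retained first and the remainder
#' is drawn by seeded sampling.
#'
#' @param leftover photo table disjoint from the training sample.
#' @param balanced_ids ids of the balanced set (retained under capping).
#' @param cap per-class ceiling (default 1000).
#' @param seed integer RNG seed.
#' @return character vector of selected photo ids (a superset of
#'   `balanced_ids`).
#' @export
imbalancedSet <- function(leftover, balanced_ids = character(0),
                          cap = 1000L, seed = 1L) {
  stopifnot(is.data.frame(leftover))
  withSeed(seed, {
    ids <- character(0)
    for (cls in sort(unique(leftover$lc1))) {
      pool <- leftover[leftover$lc1 == cls, , drop = FALSE]
      if (nrow(pool) <= cap) {
        ids <- c(ids, pool$id)
      } else {
        keep <- intersect(pool$id, balanced_ids)
        rest <- setdiff(pool$id, keep)
        ids <- c(ids, keep, resample(rest, cap - length(keep)))
      }
    }
    ids
  })
}

#' Stratified unfavorable-condition sample
#'
#' Draws at most one rejected photo per (year, class, condition) cell,
#' reporting the cells left empty.
#'
#' @param rejected photo table with `year`, `lc1`, `condition` set.
#' @param seed integer RNG seed.
#' @return character vector of ids with attribute `empty_cells`: data
#'   frame of unfilled (year, lc1, condition) combinations.
#' @export
conditionSample <- function(rejected, seed = 1L) {
  stopifnot(is.data.frame(rejected))
  years <- sort(unique(rejected$year))
  classes <- sort(unique(rejected$lc1))
  conds <- conditionLabels()
  grid <- expand.grid(year = years, lc1 = classes, condition = conds,
                      stringsAsFactors = FALSE)
  key <- paste(rejected$year, rejected$lc1, rejected$condition)
  withSeed(seed, {
    picked <- character(0)
    empty <- logical(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      ids <- rejected$id[key == paste(grid$year[i], grid$lc1[i],
                                      grid$condition[i])]
      if (length(ids) == 0L) empty[i] <- TRUE
      else picked <- c(picked, resample(ids, 1L))
    }
    attr(picked, "empty_cells") <- grid[empty, , drop = FALSE]
    picked
  })
}

#' Build all study cohorts in one pass
#'
#' Applies maturity filtering, then draws the training sample, the
#' balanced set from the leftover pool, and the capped imbalanced set
#' (which contains the balanced set).  Validates the cohort invariants:
#' training is disjoint from both inference sets and balanced is a subset
#' of imbalanced.
#'
#' @param photos photo table.
#' @param windows maturity windows (`NULL` skips maturity filtering).
#' @param n_train,n_balanced,cap cohort-size parameters (defaults 400, 85,
#'   1000).
#' @param seed integer RNG seed.
#' @return object of class `cohortSets`: list with `training`, `balanced`,
#'   `imbalanced` id vectors, the `mature` photo table used, and `summary`
#'   (per-class counts per set).
#' @export
buildCohorts <- function(photos, windows = NULL, n_train = 400L,
                         n_balanced = 85L, cap = 1000L, seed = 1L) {
  mature <- if (is.null(windows)) photos else selectMature(photos, windows)
  clean <- if ("quality" %in% names(mature))
    mature[mature$quality == "clean", , drop = FALSE] else mature
  train_ids <- trainingSample(clean, n_train, seed = seed)
  training <- clean[clean$id %in% train_ids, , drop = FALSE]
  leftover <- clean[!clean$id %in% train_ids, , drop = FALSE]
  bal_ids <- balancedSet(leftover, training, n_balanced, seed = seed + 1L)
  imb_ids <- imbalancedSet(leftover, bal_ids, cap, seed = seed + 2L)
  stopifnot(length(intersect(train_ids, imb_ids)) == 0L,
            all(bal_ids %in% imb_ids))
  perClass <- function(ids) table(factor(clean$lc1[match(ids, clean$id)],
                                         levels = sort(unique(clean$lc1))))
  out <- list(
    training = train_ids,
    balanced = bal_ids,
    imbalanced = imb_ids,
    mature = mature,
    summary = data.frame(
      lc1 = sort(unique(clean$lc1)),
      training = as.integer(perClass(train_ids)),
      balanced = as.integer(perClass(bal_ids)),
      imbalanced = as.integer(perClass(imb_ids))
    )
  )
  class(out) <- "cohortSets"
  out
}

#' @export
print.cohortSets <- function(x, ...) {
  cat(sprintf("Cohorts: %d training, %d balanced, %d imbalanced photos\n",
              length(x$training), length(x$balanced), length(x$imbalanced)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
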