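# Synthetic inputs with the statistical structure the analysis assumes:
# classifier softmax records with a cereal-confusion block and bimodal
# correct/incorrect MP marginals, photo-metadata tables shaped like the
# published per-country tallies, calendar fixtures, and tiny labelled
# images for the hyperparameter-search harness.
#
# Correct and incorrect softmax vectors are drawn from peaked Dirichlet
# distributions with separate concentration parameters: sharp for correct
# predictions (high MP/ERP) and flat for errors (low MP/ERP), which
# reproduces the bimodal maximum-probability marginals that the quadrant
# filter exploits.

#' Default per-class record counts
#'
#' The per-class totals of the validated clean-photo tally (sum 15,876),
#' so that class imbalance in generated record sets mirrors the published
#' distribution.
#'
#' @return named integer vector over the 12 LC1 classes.
#' @export
defaultClassCounts <- function() {
  tab <- lucasTable1()
  cls <- intersect(lc1Classes(), names(tab))
  setNames(as.integer(colSums(tab[cls])), cls)
}

#' Default per-class accuracy targets
#'
#' Emulates the error structure of the study setting: cereals (B11--B15)
#' and grassland (B55) are hard to separate and get low accuracy, durum
#' wheat lowest of all; maize and rapeseed are nearly always right.
#'
#' @return named numeric vector of probabilities over the 12 LC1 classes.
#' @export
defaultClassAccuracies <- function() {
  c(B11 = 0.72, B12 = 0.35, B13 = 0.65, B14 = 0.55, B15 = 0.55,
    B16 = 0.955, B21 = 0.85, B22 = 0.85, B31 = 0.88, B32 = 0.93,
    B33 = 0.80, B55 = 0.65)
}

#' Default confusion kernel (error-destination distribution)
#'
#' Row-stochastic matrix with zero diagonal giving, for each true class,
#' where its misclassifications land.  For LC1 labels a cereal block is
#' built: cereal errors go mostly to the other cereals (60%) and to
#' grassland (25%); grassland errors go mostly to cereals (70%); other
#' classes err uniformly.  Non-LC1 labels get a uniform kernel.
#'
#' @param labels character vector of class labels (k >= 2).
#' @return k x k numeric matrix with rows summing to 1.
#' @export
defaultConfusionKernel <- function(labels = lc1Classes()) {
  k <- length(labels)
  stopifnot(k >= 2L)
  K <- matrix(0, k, k, dimnames = list(labels, labels))
  cer <- intersect(labels, cerealClasses())
  for (i in seq_len(k)) {
    lab <- labels[i]
    others <- setdiff(labels, lab)
    w <- setNames(rep(1, length(others)), others)
    if (all(labels %in% lc1Classes())) {
      if (lab %in% cer) {
        oc <- setdiff(cer, lab)
        rest <- setdiff(others, c(oc, "B55"))
        w[] <- 0
        if (length(oc) > 0) w[oc] <- 0.60 / length(oc)
        if ("B55" %in% others) w["B55"] <- 0.25
        if (length(rest) > 0) w[rest] <- 0.15 / length(rest)
      } else if (lab == "B55" && length(cer) > 0) {
        rest <- setdiff(others, cer)
        w[] <- 0
        w[cer] <- 0.70 / length(cer)
        if (length(rest) > 0) w[rest] <- 0.30 / length(rest)
      }
    }
    K[i, others] <- w / sum(w)
  }
  K
}

# Dirichlet rows with per-row peak on `target`; rejection-resamples rows
# whose argmax misses the target (bounded).
rdirichletPeaked <- function(target_idx, k, conc, alpha_base,
                             max_tries = 1000L) {
  n <- length(target_idx)
  A <- matrix(alpha_base, n, k)
  A[cbind(seq_len(n), target_idx)] <- conc
  P <- matrix(0, n, k)
  todo <- seq_len(n)
  for (try in seq_len(max_tries)) {
    m <- length(todo)
    G <- matrix(rgamma(m * k, shape = as.vector(A[todo, , drop = FALSE])),
                m, k)
    P[todo, ] <- G / rowSums(G)
    hit <- max.col(P[todo, , drop = FALSE], ties.method = "first") ==
      target_idx[todo]
    todo <- todo[!hit]
    if (length(todo) == 0L) break
  }
  if (length(todo) > 0L)
    stop(sprintf("could not peak %d probability vectors on their target class after %d tries; concentration parameters make the configuration infeasible",
                 length(todo), max_tries), call. = FALSE)
  P
}

#' Generate synthetic classifier records
#'
#' For each record, the prediction is correct with the class's configured
#' accuracy; correct records get a softmax vector peaked on the true
#' class (concentration `conc_correct`), errors land on a destination
#' drawn from the confusion kernel and get a flatter vector peaked there
#' (`conc_incorrect`).  Deterministic given `seed`.
#'
#' @param counts named integer vector of record counts per class.
#' @param accuracy named numeric vector of per-class probabilities of a
#'   correct prediction; default: the study-shaped accuracies for LC1
#'   labels, 0.8 otherwise.
#' @param kernel row-stochastic confusion kernel (zero diagonal) over the
#'   same labels; default [defaultConfusionKernel()].
#' @param conc_correct,conc_incorrect Dirichlet concentration placed on
#'   the target class for correct (sharp, default 12) and incorrect
#'   (flat, default 2.5) draws.
#' @param alpha_base Dirichlet concentration of the non-target classes
#'   (default 0.4).
#' @param seed integer RNG seed.
#' @return data frame with `id`, `true_label`, one `p_<label>` column per
#'   class, `pred_label` and `correct`.
#' @examples
#' r <- genRecords(counts = c(B11 = 50, B16 = 50), seed = 7)
#' mean(r$correct)
#' @export
genRecords <- function(counts = defaultClassCounts(), accuracy = NULL,
                       kernel = NULL, conc_correct = 12,
                       conc_incorrect = 2.5, alpha_base = 0.4, seed = 1L) {
  labels <- names(counts)
  stopifnot(!is.null(labels), all(counts >= 0), length(labels) >= 2L)
  k <- length(labels)
  if (is.null(accuracy)) {
    accuracy <- if (all(labels %in% lc1Classes()))
      defaultClassAccuracies()[labels] else setNames(rep(0.8, k), labels)
  }
  stopifnot(all(accuracy >= 0 & accuracy <= 1),
            all(labels %in% names(accuracy)))
  if (is.null(kernel)) kernel <- defaultConfusionKernel(labels)
  stopifnot(nrow(kernel) == k, ncol(kernel) == k,
            max(abs(rowSums(kernel) - 1)) < 1e-9, all(diag(kernel) == 0))
  n <- sum(counts)
  true <- rep(labels, counts)
  withSeed(seed, {
    correct <- runif(n) < accuracy[true]
    target <- true
    for (lab in labels) {
      idx <- which(true == lab & !correct)
      if (length(idx) > 0L)
        target[idx] <- sample(labels, length(idx), replace = TRUE,
                              prob = kernel[lab, ])
    }
    P <- rdirichletPeaked(match(target, labels), k,
                          ifelse(correct, conc_correct, conc_incorrect),
                          alpha_base)
    # per-row concentration: rebuild alpha inside helper needs vector conc
    out <- data.frame(id = sprintf("r%06d", seq_len(n)),
                      true_label = true, stringsAsFactors = FALSE)
    for (j in seq_len(k)) out[[paste0("p_", labels[j])]] <- P[, j]
    out$pred_label <- labels[max.col(P, ties.method = "first")]
    out$correct <- out$pred_label == out$true_label
    out
  })
}

#' Default resolution mix for generated photos
#'
#' Dominated by 1600 x 1200 (about two thirds) with a 2048 x 1536 second
#' mode and a long tail of other native camera resolutions spanning
#' 640 x 480 up to 4672 x 3504, as accumulates in a multi-year survey
#' shot on heterogeneous devices.
#'
#' @return data frame `width`, `height`, `prob`.
#' @export
defaultResolutionMix <- function() {
  data.frame(
    width = c(1600, 2048, 640, 800, 1024, 1280, 2272, 2560, 3072, 3264,
              4000, 4672),
    height = c(1200, 1536, 480, 600, 768, 960, 1704, 1920, 2304, 2448,
               3000, 3504),
    prob = c(0.66, 0.22, 0.01, 0.01, 0.015, 0.015, 0.015, 0.015, 0.01,
             0.01, 0.01, 0.01)
  )
}

hmToDate <- function(hm, year) {
  month <- ceiling(hm / 2)
  day <- ifelse(hm %% 2 == 1, 8L, 20L)
  as.Date(sprintf("%d-%02d-%02d", year, month, day))
}

#' Generate a photo-metadata table
#'
#' Produces photo records per (country, class) cell with survey dates
#' placed inside or outside the cell's maturity window according to
#' `in_window_frac`, native resolutions drawn from `resolution_mix`, and
#' optionally a block of rejected photos tagged with unfavorable
#' conditions (one block per year x class x condition cell).
#'
#' @param counts data frame of per-country clean-photo counts: a
#'   `country` column plus one column per class.  Default: the published
#'   tally, optionally scaled.
#' @param scale multiplier applied to the default counts (rounded up, so
#'   small scales keep every non-empty cell occupied).
#' @param windows maturity-window table (`country`, `crop`, `start_hm`,
#'   `end_hm`) or `NULL` for uniform dates.
#' @param in_window_frac probability that a photo's date falls inside its
#'   maturity window (default 0.9).
#' @param years survey years to draw from.
#' @param resolution_mix data frame `width`, `height`, `prob`.
#' @param rejected_per_cell number of rejected (condition-tagged) photos
#'   per (year, class, condition) cell (default 0).
#' @param seed integer RNG seed.
#' @return photo table: `id`, `country`, `lc1`, `date`, `year`, `width`,
#'   `height`, `quality`, `condition`.
#' @export
genPhotoTable <- function(counts = NULL, scale = 1, windows = NULL,
                          in_window_frac = 0.9,
                          years = c(2006L, 2009L, 2012L, 2015L, 2018L),
                          resolution_mix = defaultResolutionMix(),
                          rejected_per_cell = 0L, seed = 1L) {
  if (is.null(counts)) {
    counts <- lucasTable1()
    counts <- counts[c("country", intersect(lc1Classes(), names(counts)))]
  }
  classes <- setdiff(names(counts), "country")
  if (scale != 1) {
    counts[classes] <- lapply(counts[classes],
                              function(x) as.integer(ceiling(x * scale)))
  }
  wkey <- if (is.null(windows)) character(0) else
    paste(windows$country, windows$crop)
  withSeed(seed, {
    rows <- list()
    for (i in seq_len(nrow(counts))) {
      for (cls in classes) {
        n <- counts[[cls]][i]
        if (n == 0L) next
        ctry <- counts$country[i]
        wi <- match(paste(ctry, cls), wkey)
        if (!is.null(windows) && !is.na(wi)) {
          win <- hmWrap(seq(windows$start_hm[wi],
                            windows$start_hm[wi] +
                              hmLength(windows$start_hm[wi],
                                       windows$end_hm[wi]) - 1L))
          outside <- setdiff(1:24, win)
          inside <- runif(n) < in_window_frac
          if (length(outside) == 0L) inside[] <- TRUE
          hm <- integer(n)
          hm[inside] <- win[sample.int(length(win), sum(inside),
                                       replace = TRUE)]
          if (any(!inside))
            hm[!inside] <- outside[sample.int(length(outside), sum(!inside),
                                              replace = TRUE)]
        } else {
          hm <- sample.int(24L, n, replace = TRUE)
        }
        yr <- years[sample.int(length(years), n, replace = TRUE)]
        res <- sample.int(nrow(resolution_mix), n, replace = TRUE,
                          prob = resolution_mix$prob)
        rows[[length(rows) + 1L]] <- data.frame(
          country = ctry, lc1 = cls, date = hmToDate(hm, yr), year = yr,
          width = resolution_mix$width[res],
          height = resolution_mix$height[res],
          quality = "clean", condition = NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    if (rejected_per_cell > 0L) {
      grid <- expand.grid(year = years, lc1 = classes,
                          condition = conditionLabels(),
                          stringsAsFactors = FALSE)
      nrej <- nrow(grid) * rejected_per_cell
      gi <- rep(seq_len(nrow(grid)), each = rejected_per_cell)
      res <- sample.int(nrow(resolution_mix), nrej, replace = TRUE,
                        prob = resolution_mix$prob)
      rej <- data.frame(
        country = counts$country[sample.int(nrow(counts), nrej,
                                            replace = TRUE)],
        lc1 = grid$lc1[gi],
        date = hmToDate(sample.int(24L, nrej, replace = TRUE),
                        grid$year[gi]),
        year = grid$year[gi],
        width = resolution_mix$width[res],
        height = resolution_mix$height[res],
        quality = "rejected", condition = grid$condition[gi],
        stringsAsFactors = FALSE
      )
      out <- rbind(out, rej)
    }
    out$id <- sprintf("p%07d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out[c("id", "country", "lc1", "date", "year", "width", "height",
          "quality", "condition")]
  })
}

#' Generate a crop-calendar fixture
#'
#' Harvest windows of plausible length (2--6 half-months) around
#' crop-typical harvest periods, with optional variety conflicts injected
#' for testing harmonization (a spring entry next to a winter one for
#' cereals/rapeseed, a late-ware entry next to an early one for potatoes).
#'
#' @param countries character vector of country codes.
#' @param crops character vector of crop codes (default: the 12 LC1
#'   classes).
#' @param conflict_frac fraction of eligible (country, crop) cells that
#'   receive a conflicting variety entry.
#' @param seed integer RNG seed.
#' @return calendar entry table: `country`, `crop`, `variety`, `stage`,
#'   `start_hm`, `end_hm`, `provenance`.
#' @export
genCalendarFixture <- function(countries, crops = lc1Classes(),
                               conflict_frac = 0, seed = 1L) {
  typical <- c(B11 = 13L, B12 = 13L, B13 = 13L, B14 = 13L, B15 = 14L,
               B16 = 18L, B21 = 17L, B22 = 19L, B31 = 17L, B32 = 14L,
               B33 = 18L, B55 = 10L)
  pairable <- c(cerealClasses(), "B32", "B21")
  withSeed(seed, {
    rows <- list()
    for (ctry in countries) {
      for (crop in crops) {
        base <- if (crop %in% names(typical)) typical[[crop]] else 13L
        start <- hmWrap(base + sample(-1:1, 1L))
        len <- sample(2:6, 1L)
        conflict <- crop %in% pairable && runif(1) < conflict_frac
        variety <- if (conflict) {
          if (crop == "B21") "early" else "winter"
        } else "single"
        prov <- sample(c("official_cc", "expert", "model"), 1L,
                       prob = c(0.8, 0.15, 0.05))
        rows[[length(rows) + 1L]] <- data.frame(
          country = ctry, crop = crop, variety = variety,
          stage = "harvest", start_hm = start,
          end_hm = hmWrap(start + len - 1L), provenance = prov,
          stringsAsFactors = FALSE
        )
        if (conflict) {
          alt_start <- hmWrap(start + sample(2:4, 1L))
          rows[[length(rows) + 1L]] <- data.frame(
            country = ctry, crop = crop,
            variety = if (crop == "B21") "late" else "spring",
            stage = "harvest", start_hm = alt_start,
            end_hm = hmWrap(alt_start + sample(2:6, 1L) - 1L),
            provenance = prov, stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate tiny labelled images with class-specific statistics
#'
#' Desk-scale stand-ins for crop photos: each class has a mean intensity
#' and a sinusoidal texture frequency, plus Gaussian pixel noise, so a
#' small classifier can separate classes whose parameters differ and is
#' at chance when all classes share parameters.
#'
#' @param labels class labels.
#' @param n_per_class images per class.
#' @param size image side length in pixels (square images).
#' @param class_params optional data frame `mu`, `freq`, `amp` with one
#'   row per class; default spreads means over `[0.2, 0.8]`.
#' @param noise standard deviation of pixel noise.
#' @param seed integer RNG seed.
#' @return list with `x` (list of `size` x `size` matrices in `[0, 1]`)
#'   and `y` (character labels).
#' @export
genImages <- function(labels = c("A", "B", "C"), n_per_class = 20L,
                      size = 16L, class_params = NULL, noise = 0.08,
                      seed = 1L) {
  k <- length(labels)
  if (is.null(class_params)) {
    class_params <- data.frame(
      mu = seq(0.2, 0.8, length.out = k),
      freq = seq(1, k),
      amp = rep(0.15, k)
    )
  }
  stopifnot(nrow(class_params) == k)
  grid <- matrix(seq_len(size), size, size)
  withSeed(seed, {
    x <- vector("list", k * n_per_class)
    y <- character(k * n_per_class)
    idx <- 0L
    for (i in seq_len(k)) {
      tex <- class_params$amp[i] *
        sin(2 * pi * class_params$freq[i] * grid / size)
      for (j in seq_len(n_per_class)) {
        idx <- idx + 1L
        img <- class_params$mu[i] + tex +
          matrix(rnorm(size * size, sd = noise), size, size)
        x[[idx]] <- pmin(pmax(img, 0), 1)
        y[idx] <- labels[i]
      }
    }
    list(x = x, y = y)
  })
}
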