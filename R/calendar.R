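# Crop-calendar harmonization and maturity windowing.
#
# Time is measured in half-months: index 2m-1 is the first half (days
# 1-15) of month m, index 2m the second half, giving a circular 1..24
# scale that wraps across the year boundary.  Mature pre-harvest windows
# are derived from harvest windows by dropping the last half-month and
# extending the start backwards by a crop-group-specific amount: two
# months (4 half-months) for cereals, rapeseed, sunflower and soya; three
# months (6 half-months) for potatoes, sugar beet, maize and rice.

#' Wrap a half-month index onto the circular 1..24 scale
#'
#' @param i integer (possibly out of range); arithmetic is modulo 24.
#' @return integer in 1..24.
#' @export
hmWrap <- function(i) {
  as.integer(((i - 1L) %% 24L) + 1L)
}

#' Length of a half-month window, inclusive of both ends
#'
#' Wrapping windows (start > end) are measured across the year boundary.
#'
#' @param start,end half-month indices in 1..24.
#' @return integer length in half-months, in 1..24.
#' @export
hmLength <- function(start, end) {
  as.integer(ifelse(start <= end, end - start + 1L,
                    24L - start + 1L + end))
}

#' Convert a calendar date to its half-month index
#'
#' Days 1--15 map to the first half of the month, days 16 and later to the
#' second half.
#'
#' @param date a `Date` or anything `as.Date()` accepts.
#' @return integer half-month index in 1..24.
#' @examples
#' dateToHalfMonth("2018-07-01")  # 13
#' dateToHalfMonth("2018-12-31")  # 24
#' @export
dateToHalfMonth <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) NA)
  if (anyNA(d)) stop("invalid date", call. = FALSE)
  m <- as.integer(format(d, "%m"))
  day <- as.integer(format(d, "%d"))
  as.integer(ifelse(day <= 15L, 2L * m - 1L, 2L * m))
}

#' Test whether a half-month falls inside a (possibly wrapping) window
#'
#' Membership is inclusive; a window with start > end wraps across the
#' year end.
#'
#' @param start,end window bounds (half-month indices).
#' @param hm half-month index to test.
#' @return logical.
#' @examples
#' windowContains(9, 15, 13)   # TRUE
#' windowContains(21, 1, 24)   # TRUE (wraps)
#' @export
windowContains <- function(start, end, hm) {
  ifelse(start <= end, hm >= start & hm <= end,
         hm >= start | hm <= end)
}

#' Maturity-extension rule table
#'
#' Crops fall in two groups: group A (cereals B11--B15, sunflower B31,
#' rapeseed B32, soya B33) gets a 2-month (4 half-month) backward
#' extension; group B (maize B16, potatoes B21, sugar beet B22, and rice,
#' kept for completeness) gets 3 months (6 half-months).  Temporary
#' grassland (B55) has no rule and needs an explicit override window.
#'
#' @return data frame with columns `crop` and `extension` (half-months).
#' @export
maturityRules <- function() {
  data.frame(
    crop = c("B11", "B12", "B13", "B14", "B15", "B31", "B32", "B33",
             "B16", "B21", "B22", "RICE"),
    extension = c(rep(4L, 8L), rep(6L, 4L)),
    stringsAsFactors = FALSE
  )
}

#' Derive the mature pre-harvest window from a harvest window
#'
#' Removes the last half-month of the harvest stage (`end - 1`) and moves
#' the start back by the crop's extension (4 or 6 half-months), modulo 24.
#' Crops without a rule (e.g. temporary grassland B55) must be given an
#' explicit override window; the default override keeps B55 open all year.
#'
#' @param start,end harvest-stage bounds (half-month indices 1..24).
#' @param crop LC1 crop code (or `"RICE"`).
#' @param overrides named list of `c(start, end)` windows for crops
#'   outside the rule table.
#' @return list with `start`, `end` (half-month indices) and `overridden`
#'   (logical flag).
#' @examples
#' deriveMaturityWindow(13, 16, "B11")  # (9, 15)
#' deriveMaturityWindow(17, 20, "B16")  # (11, 19)
#' deriveMaturityWindow(1, 2, "B11")    # (21, 1): wraps
#' @export
deriveMaturityWindow <- function(start, end, crop,
                                 overrides = list(B55 = c(1L, 24L))) {
  stopifnot(length(start) == 1L, length(end) == 1L)
  if (start < 1 || start > 24 || end < 1 || end > 24)
    stop("harvest window bounds must lie in 1..24", call. = FALSE)
  rules <- maturityRules()
  i <- match(crop, rules$crop)
  if (is.na(i)) {
    if (!is.null(overrides[[crop]])) {
      w <- overrides[[crop]]
      return(list(start = hmWrap(w[1]), end = hmWrap(w[2]),
                  overridden = TRUE))
    }
    stop(sprintf("no maturity rule for crop '%s' and no override window configured",
                 crop), call. = FALSE)
  }
  list(start = hmWrap(start - rules$extension[i]),
       end = hmWrap(end - 1L),
       overridden = FALSE)
}

#' Derive maturity windows for a whole harmonized calendar table
#'
#' @param calendar harmonized calendar table (see [harmonizeCalendar()])
#'   with columns `country`, `crop`, `start_hm`, `end_hm`.
#' @param overrides passed to [deriveMaturityWindow()].
#' @return data frame `country`, `crop`, `start_hm`, `end_hm`,
#'   `overridden` -- one maturity window per (country, crop).
#' @export
deriveMaturityWindows <- function(calendar,
                                  overrides = list(B55 = c(1L, 24L))) {
  stopifnot(is.data.frame(calendar))
  rows <- lapply(seq_len(nrow(calendar)), function(i) {
    w <- deriveMaturityWindow(calendar$start_hm[i], calendar$end_hm[i],
                              calendar$crop[i], overrides)
    data.frame(country = calendar$country[i], crop = calendar$crop[i],
               start_hm = w$start, end_hm = w$end,
               overridden = w$overridden, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(country = character(0), crop = character(0),
                      start_hm = integer(0), end_hm = integer(0),
                      overridden = logical(0)))
  do.call(rbind, rows)
}

#' Harmonize raw crop-calendar entries to one harvest window per cell
#'
#' Reduces a stack of calendar entries to a canonical table with one
#' harvest window per (country, crop).  Where a country cultivates both
#' members of a variety pair (winter/spring, or early/late ware), only the
#' winter resp. early-ware entry is kept and the row is flagged as
#' variety-conflict-resolved.  Entries whose provenance is expert
#' knowledge or model output pass through with a `gap_filled` flag.
#' Distinct windows for the same (country, crop, variety) are
#' contradictory and raise an error listing them.  The operation is
#' idempotent.
#'
#' @param entries data frame with columns `country`, `crop`, `variety`
#'   (winter/spring/early/late/single), `stage`, `start_hm`, `end_hm`,
#'   `provenance` (official_cc/expert/model).  Only `stage == "harvest"`
#'   rows are used; a missing `stage` column means all rows are harvest.
#' @return data frame `country`, `crop`, `variety`, `stage`, `start_hm`,
#'   `end_hm`, `provenance`, `variety_conflict`, `gap_filled`.
#' @export
harmonizeCalendar <- function(entries) {
  stopifnot(is.data.frame(entries))
  empty <- data.frame(country = character(0), crop = character(0),
                      variety = character(0), stage = character(0),
                      start_hm = integer(0), end_hm = integer(0),
                      provenance = character(0),
                      variety_conflict = logical(0),
                      gap_filled = logical(0), stringsAsFactors = FALSE)
  if (nrow(entries) == 0L) return(empty)
  if (!"stage" %in% names(entries)) entries$stage <- "harvest"
  if (!"variety" %in% names(entries)) entries$variety <- "single"
  if (!"provenance" %in% names(entries)) entries$provenance <- "official_cc"
  ent <- entries[entries$stage == "harvest", , drop = FALSE]
  if (nrow(ent) == 0L) return(empty)
  ent <- unique(ent[c("country", "crop", "variety", "start_hm", "end_hm",
                      "provenance")])

  # contradictory duplicates: same (country, crop, variety), different window
  key <- paste(ent$country, ent$crop, ent$variety)
  dup <- key[duplicated(key)]
  if (length(dup) > 0L) {
    bad <- ent[key %in% dup, , drop = FALSE]
    stop("contradictory harvest windows for: ",
         paste(unique(paste(bad$country, bad$crop, bad$variety)),
               collapse = "; "), call. = FALSE)
  }

  cellkey <- paste(ent$country, ent$crop)
  prev_conflict <- if ("variety_conflict" %in% names(entries))
    entries$variety_conflict[entries$stage == "harvest"] else
      rep(FALSE, nrow(ent))
  out <- lapply(split(seq_len(nrow(ent)), cellkey), function(idx) {
    cell <- ent[idx, , drop = FALSE]
    conflict <- FALSE
    vs <- cell$variety
    if (all(c("winter", "spring") %in% vs)) {
      cell <- cell[cell$variety != "spring", , drop = FALSE]
      conflict <- TRUE
    }
    if (all(c("early", "late") %in% cell$variety)) {
      cell <- cell[cell$variety != "late", , drop = FALSE]
      conflict <- TRUE
    }
    if (nrow(cell) > 1L)
      stop("ambiguous varieties for ", cell$country[1], " ", cell$crop[1],
           ": ", paste(cell$variety, collapse = ", "), call. = FALSE)
    cell$variety_conflict <- conflict
    cell
  })
  out <- do.call(rbind, out)
  # keep a previously set conflict flag across re-runs (idempotence)
  if (any(prev_conflict)) {
    prevkey <- paste(ent$country, ent$crop)[prev_conflict]
    out$variety_conflict <- out$variety_conflict |
      paste(out$country, out$crop) %in% prevkey
  }
  out$gap_filled <- out$provenance != "official_cc"
  out$stage <- "harvest"
  out <- out[order(out$country, out$crop),
             c("country", "crop", "variety", "stage", "start_hm", "end_hm",
               "provenance", "variety_conflict", "gap_filled")]
  rownames(out) <- NULL
  out
}
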