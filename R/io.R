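# Plain-CSV readers and writers for the tables the pipeline exchanges.

#' Read a classifier-record CSV
#'
#' Expected columns: `id`, `true_label` and one `p_<label>` column per
#' class; scored tables may additionally carry `pred_label`, `mp`,
#' `entropy`, `divergence`, `erp`.
#'
#' @param path file path.
#' @return record data frame.
#' @export
readRecordsCsv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  probColumns(out)  # validates presence of p_* columns
  if (!all(c("id", "true_label") %in% names(out)))
    stop("records CSV needs id and true_label columns", call. = FALSE)
  out
}

#' Write a (scored) record table to CSV
#'
#' @param records record data frame.
#' @param path file path.
#' @export
writeRecordsCsv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a crop-calendar CSV
#'
#' Expected columns: `country`, `crop`, `variety`, `stage`, `start_hm`,
#' `end_hm`, `provenance`.
#'
#' @param path file path.
#' @return calendar entry data frame.
#' @export
readCalendarCsv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "crop", "start_hm", "end_hm")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0L)
    stop("calendar CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out
}

#' Read a photo-metadata CSV
#'
#' Expected columns: `id`, `country`, `lc1`, `date`, `width`, `height`,
#' `quality`, `condition` (condition may be empty for clean photos).
#'
#' @param path file path.
#' @return photo data frame with `date` parsed and `year` derived if
#'   absent.
#' @export
readPhotoCsv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "country", "lc1", "date")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0L)
    stop("photo CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out$date <- as.Date(out$date)
  if (!"year" %in% names(out))
    out$year <- as.integer(format(out$date, "%Y"))
  out
}
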