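#' Banding-record tables
#'
#' Individual banding/encounter records are carried as a plain
#' data.frame with six columns: `band_id`, `band_type`, `banding_date`
#' (Date), `banding_region`, `recovery_date` (Date, `NA` when the bird
#' was never reported), `recovery_region` (`NA` likewise). Region labels
#' are always canonical per [regionRegistry()]; the two recovery fields
#' are either both present or both absent, and `recovery_date >=
#' banding_date`.
#'
#' @name banding-records
NULL

RECORD_COLS <- c("band_id", "band_type", "banding_date", "banding_region",
                 "recovery_date", "recovery_region")

# row-wise invariant check; returns character(0) when clean, else one
# message per offending row index
recordProblems <- function(df) {
  prob <- character()
  bad_bd <- is.na(df$banding_date)
  has_rd <- !is.na(df$recovery_date)
  has_rr <- !is.na(df$recovery_region) & nzchar(as.character(df$recovery_region))
  mismatch <- xor(has_rd, has_rr)
  bad_reg <- is.na(normalizeRegion(df$banding_region))
  bad_rreg <- has_rr & is.na(normalizeRegion(df$recovery_region))
  bad_order <- has_rd & !is.na(df$banding_date) & df$recovery_date < df$banding_date
  bad <- bad_bd | mismatch | bad_reg | bad_rreg | bad_order
  if (any(bad)) {
    why <- ifelse(bad_bd, "unparseable banding_date",
           ifelse(mismatch, "recovery_date/recovery_region must both be present or both absent",
           ifelse(bad_reg, "unknown banding_region",
           ifelse(bad_rreg, "unknown recovery_region",
                  "recovery_date before banding_date"))))
    prob <- paste0("row ", which(bad), ": ", why[bad])
  }
  prob
}

#' Load banding records from CSV
#'
#' Reads a flat table of banding/encounter records (one row per banded
#' bird, recovery fields empty when the band was never reported), in the
#' layout of a BBL-style export: columns `band_id`, `band_type`,
#' `banding_date`, `banding_region`, `recovery_date`, `recovery_region`,
#' ISO-8601 (`YYYY-MM-DD`) dates, UTF-8. Differently named columns can
#' be adapted with `col_map`.
#'
#' Region labels are normalized to the canonical seven-region registry.
#' In strict mode any malformed row aborts with a message naming it; in
#' non-strict mode malformed rows are dropped and the count reported via
#' `message()` (and the `"n_dropped"` attribute).
#'
#' @param path CSV file path.
#' @param strict abort on malformed rows (default TRUE) instead of
#'   dropping them.
#' @param col_map optional named character vector mapping canonical
#'   column names to the file's column names, e.g.
#'   `c(band_id = "BAND_NUM")`.
#' @return data.frame of validated records (see [banding-records]),
#'   with attribute `n_dropped` (0 in strict mode).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(band_id = "b1", band_type = "mail_in",
#'   banding_date = "1960-08-15", banding_region = "NE Canada",
#'   recovery_date = "1960-11-02", recovery_region = "S Atlantic"),
#'   f, row.names = FALSE)
#' loadRecords(f)
#' @export
loadRecords <- function(path, strict = TRUE, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(raw))
        stop("col_map names missing column '", col_map[[canon]], "'",
             call. = FALSE)
      names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  }
  missing <- setdiff(RECORD_COLS, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- raw[, RECORD_COLS]
  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  df$recovery_date[blank(df$recovery_date)] <- NA
  df$recovery_region[blank(df$recovery_region)] <- NA
  df$banding_date <- as.Date(df$banding_date, format = "%Y-%m-%d")
  df$recovery_date <- as.Date(df$recovery_date, format = "%Y-%m-%d")

  prob <- recordProblems(df)
  n_dropped <- 0L
  if (length(prob)) {
    if (strict)
      stop("invalid record(s):\n  ", paste(prob, collapse = "\n  "),
           call. = FALSE)
    bad <- as.integer(sub("^row ([0-9]+):.*$", "\\1", prob))
    n_dropped <- length(unique(bad))
    message("loadRecords: dropped ", n_dropped, " malformed row(s)")
    df <- df[-unique(bad), , drop = FALSE]
  }
  df$banding_region <- normalizeRegion(df$banding_region)
  df$recovery_region <- ifelse(is.na(df$recovery_region), NA_character_,
                               normalizeRegion(df$recovery_region))
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Write banding records to CSV
#'
#' Inverse of [loadRecords()]: a write-then-load round-trip is the
#' identity on valid records.
#'
#' @param records a banding-record data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRecords <- function(records, path) {
  out <- records[, RECORD_COLS]
  out$banding_date <- format(out$banding_date, "%Y-%m-%d")
  out$recovery_date <- ifelse(is.na(out$recovery_date), "",
                              format(out$recovery_date, "%Y-%m-%d"))
  out$recovery_region <- ifelse(is.na(out$recovery_region), "",
                                out$recovery_region)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a movement-probability summary table
#'
#' Emits the display table — banding regions as rows, encounter regions
#' as columns, each cell formatted `"mean (sd)"` — plus a
#' machine-readable long-format companion with one row per (banding
#' region, recovery region) cell and columns `banding_region,
#' recovery_region, mean, sd, ci_low, ci_high`.
#'
#' @param summary a [PosteriorSummary-class] covering all cells.
#' @param path path of the display CSV; the long-format companion goes
#'   to `long_path`.
#' @param long_path path of the long-format CSV (default: `path` with
#'   `_long` inserted before the extension).
#' @param digits decimals in the display cells (default 3).
#' @return invisibly, a list with both paths.
#' @export
writeSummaryTable <- function(summary, path,
                              long_path = sub("(\\.[^.]*)?$", "_long\\1", path),
                              digits = 3) {
  stopifnot(is(summary, "PosteriorSummary"))
  rn <- summary@regions
  fmt <- sprintf("%%.%df (%%.%df)", digits, digits)
  disp <- matrix(sprintf(fmt, summary@mean, summary@sd),
                 nrow = length(rn), dimnames = list(rn, rn))
  disp_df <- data.frame(banding_region = rn, disp, check.names = FALSE,
                        stringsAsFactors = FALSE)
  utils::write.csv(disp_df, path, row.names = FALSE)
  long <- summaryToLong(summary)
  utils::write.csv(long, long_path, row.names = FALSE)
  invisible(list(path = path, long_path = long_path))
}

#' @rdname writeSummaryTable
#' @return `summaryToLong`: the long-format data.frame (49 rows for the
#'   full seven-region analysis).
#' @export
summaryToLong <- function(summary) {
  stopifnot(is(summary, "PosteriorSummary"))
  rn <- summary@regions
  K <- length(rn)
  data.frame(
    banding_region = rep(rn, each = K),
    recovery_region = rep(rn, times = K),
    mean = as.vector(t(summary@mean)),
    sd = as.vector(t(summary@sd)),
    ci_low = as.vector(t(summary@ciLow)),
    ci_high = as.vector(t(summary@ciHigh)),
    stringsAsFactors = FALSE
  )
}

#' Read a long-format summary CSV back into matrices
#'
#' @param path long-format CSV written by [writeSummaryTable()].
#' @return list of matrices `mean`, `sd`, `ci_low`, `ci_high` with
#'   region dimnames.
#' @export
readSummaryLong <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  rn <- unique(long$banding_region)
  K <- length(rn)
  shape <- function(v) matrix(v, K, K, byrow = TRUE, dimnames = list(rn, rn))
  lapply(list(mean = long$mean, sd = long$sd,
              ci_low = long$ci_low, ci_high = long$ci_high), shape)
}

#' Write a posterior summary as JSON
#'
#' @param summary a [PosteriorSummary-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummaryJson <- function(summary, path) {
  stopifnot(is(summary, "PosteriorSummary"))
  obj <- list(
    regions = summary@regions,
    weights = as.list(summary@weights),
    mean = summary@mean, sd = summary@sd,
    ci_low = summary@ciLow, ci_high = summary@ciHigh
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
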