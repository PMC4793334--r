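#' Hunting-season label of a date
#'
#' Hunting seasons straddle the new year (Oct-Feb by default), so each
#' season is labelled by the calendar year in which it starts: Oct-Dec
#' dates map to their own year, Jan-Feb dates to the previous year.
#' Dates outside the hunting months get `NA` ("not in season").
#'
#' @param date a Date vector.
#' @param cfg a [FilterConfig-class] (default [filterConfig()]).
#' @return integer vector of season start years, `NA` where the month is
#'   not a hunting month.
#' @examples
#' seasonOf(as.Date(c("1971-01-15", "1970-11-30", "1970-08-01")))
#' # 1970 1970 NA
#' @export
seasonOf <- function(date, cfg = filterConfig()) {
  stopifnot(is(cfg, "FilterConfig"))
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  season <- ifelse(m >= 7L, y, y - 1L)   # Jul-Dec start the season year; Jan-Jun belong to the prior year's season
  season[!m %in% cfg@huntingMonths] <- NA_integer_
  season
}

# is a month-day within the (non-wrapping) preseason window?
inPreseason <- function(date, cfg) {
  md <- format(date, "%m-%d")
  md >= cfg@preseasonStart & md <= cfg@preseasonEnd
}

#' Apply the record-selection rules
#'
#' A record survives when, in order: (a) its banding date falls in the
#' preseason window; (b) it has a recovery; (c) the recovery month is a
#' hunting-season month; (d) it is not a direct same-region recovery —
#' recovered in the hunting season immediately following its banding
#' period, in the region where it was banded (such a bird had no
#' opportunity to move). The audit reports how many records each rule
#' removed; a record is attributed to the first rule that rejects it, so
#' the audit counts are reproducible.
#'
#' Filtering is idempotent and order-independent.
#'
#' @param records banding-record data.frame (see [banding-records]).
#' @param cfg a [FilterConfig-class].
#' @return list with `kept` (the surviving records) and `audit` (named
#'   integer drop counts: `not_preseason`, `no_recovery`,
#'   `not_hunting_season`, `direct_same_region`).
#' @examples
#' recs <- data.frame(band_id = c("a", "b"), band_type = "mail_in",
#'   banding_date = as.Date("1960-08-15"), banding_region = "NE Canada",
#'   recovery_date = as.Date("1960-11-02"),
#'   recovery_region = c("NE Canada", "S Atlantic"))
#' filterRecords(recs)$audit  # "a" is a direct same-region recovery
#' @export
filterRecords <- function(records, cfg = filterConfig()) {
  stopifnot(is(cfg, "FilterConfig"))
  n <- nrow(records)
  keep <- rep(TRUE, n)
  audit <- c(not_preseason = 0L, no_recovery = 0L,
             not_hunting_season = 0L, direct_same_region = 0L)

  a <- inPreseason(records$banding_date, cfg)
  audit["not_preseason"] <- sum(keep & !a)
  keep <- keep & a

  b <- !is.na(records$recovery_date)
  audit["no_recovery"] <- sum(keep & !b)
  keep <- keep & b

  rec_season <- rep(NA_integer_, n)
  rec_season[b] <- seasonOf(records$recovery_date[b], cfg)
  cc <- !is.na(rec_season)
  audit["not_hunting_season"] <- sum(keep & !cc)
  keep <- keep & cc

  if (cfg@dropDirectSameRegion) {
    band_year <- as.integer(format(records$banding_date, "%Y"))
    direct <- !is.na(rec_season) & rec_season == band_year &
      !is.na(records$recovery_region) &
      records$recovery_region == records$banding_region
    audit["direct_same_region"] <- sum(keep & direct)
    keep <- keep & !direct
  }

  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "n_dropped") <- NULL
  list(kept = kept, audit = audit)
}

#' Tally banded totals from records
#'
#' The banded total \eqn{N_i} per (band type, region) is the number of
#' birds banded, recovered or not — it is tallied from the full record
#' set before filtering (recoveries alone cannot give \eqn{N}).
#'
#' @param records banding-record data.frame (pre-filter, i.e. including
#'   never-recovered birds).
#' @param cfg a [FilterConfig-class]; only preseason bandings are
#'   counted, matching the filtered recoveries.
#' @return data.frame `band_type, region, n_banded`.
#' @export
tallyBandedTotals <- function(records, cfg = filterConfig()) {
  pres <- records[inPreseason(records$banding_date, cfg), , drop = FALSE]
  agg <- stats::aggregate(list(n_banded = rep(1L, nrow(pres))),
                          by = list(band_type = pres$band_type,
                                    region = pres$banding_region),
                          FUN = sum)
  agg[order(agg$band_type, match(agg$region, regionNames())), ,
      drop = FALSE]
}

#' Build per-band-type recovery matrices
#'
#' Counts the filtered recoveries into one [RecoveryMatrix-class] per
#' band type present: `D[i, j]` is the number of birds banded in region
#' `i` and recovered in region `j`. Banded totals `N` come from
#' `banded_totals` (a separate table, because recoveries alone cannot
#' give them; see [tallyBandedTotals()]).
#'
#' @param records filtered banding records (every row has a recovery).
#' @param banded_totals data.frame `band_type, region, n_banded`.
#' @return named list of [RecoveryMatrix-class], one per band type, in
#'   alphabetical band-type order.
#' @export
buildRecoveryMatrices <- function(records, banded_totals) {
  if (any(is.na(records$recovery_region)))
    stop("records must be filtered: found rows without a recovery",
         call. = FALSE)
  rn <- regionNames()
  banded_totals$region <- assertRegions(banded_totals$region)
  records$banding_region <- assertRegions(records$banding_region,
                                          "banding_region")
  records$recovery_region <- assertRegions(records$recovery_region,
                                           "recovery_region")
  types <- sort(unique(records$band_type))
  out <- lapply(types, function(k) {
    sub <- records[records$band_type == k, , drop = FALSE]
    D <- table(factor(sub$banding_region, levels = rn),
               factor(sub$recovery_region, levels = rn))
    D <- matrix(as.integer(D), N_REGIONS, N_REGIONS,
                dimnames = list(rn, rn))
    bt <- banded_totals[banded_totals$band_type == k, , drop = FALSE]
    N <- stats::setNames(rep(0L, N_REGIONS), rn)
    N[bt$region] <- as.integer(bt$n_banded)
    short <- rowSums(D) > N
    if (any(short))
      stop("band type '", k, "': recoveries exceed banded totals in ",
           paste(rn[short], collapse = ", "),
           " (inconsistent inputs)", call. = FALSE)
    yrs <- as.integer(format(sub$banding_date, "%Y"))
    recovery_yrs <- as.integer(format(sub$recovery_date, "%Y"))
    span <- if (nrow(sub)) c(min(yrs), max(recovery_yrs))
            else c(NA_integer_, NA_integer_)
    recoveryMatrix(k, D, N, span)
  })
  stats::setNames(out, types)
}
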