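#' Simulate a banding/recovery dataset with known truth
#'
#' Generative inverse of the movement model: every bird in each cohort
#' `(band_type k, region i, year y)` is banded on a uniform date in the
#' preseason window, moves to a destination drawn from row `i` of the
#' true movement matrix, and is independently recovered-and-reported
#' with probability `lambda_k * h` (harvest and reporting collapsed
#' into one Bernoulli, mirroring the model's confounding). Recovered
#' birds get a hunting-season recovery date in a season one to three
#' years after banding — never the direct season, so no clean record
#' can trip the direct-recovery filter. The ledger records the exact
#' per-cell recovery counts per band type, so
#' simulate -> filter -> [buildRecoveryMatrices()] can be checked for
#' exact reconstruction.
#'
#' With `filter_noise = TRUE`, extra records violating each filter rule
#' are planted (out-of-preseason bandings, out-of-season recoveries,
#' direct same-region recoveries) and their exact counts recorded in
#' `ledger$planted`, so filter audits can be verified against truth.
#'
#' @param truth a [SyntheticTruth-class].
#' @param filter_noise plant filter-rule violations (default FALSE).
#' @return list with `records` (banding-record data.frame, see
#'   [banding-records]) and `ledger`: `D` (named list of 7x7 true
#'   recovery-count matrices per band type), `n_unrecovered` (clean
#'   birds never reported), and `planted` (named counts of planted
#'   rule violations).
#' @examples
#' truth <- blackDuckScenario(seed = 1)
#' truth@cohorts <- truth@cohorts[truth@cohorts$year == 1980, ]
#' sim <- simulateDataset(truth)
#' nrow(sim$records)
#' @export
simulateDataset <- function(truth, filter_noise = FALSE) {
  stopifnot(is(truth, "SyntheticTruth"))
  set.seed(truth@seed)
  rn <- regionNames()
  co <- truth@cohorts[truth@cohorts$n > 0, , drop = FALSE]
  idx <- rep(seq_len(nrow(co)), co$n)
  n <- length(idx)
  band_type <- co$band_type[idx]
  region_i <- co$region[idx]
  year <- co$year[idx]

  # preseason banding dates: uniform over 1 Jul - 30 Sep (92 days)
  banding_date <- as.Date(paste0(year, "-07-01")) +
    sample.int(92L, n, replace = TRUE) - 1L

  # destination per bird from the true movement row
  dest <- integer(n)
  ii <- match(region_i, rn)
  for (i in seq_along(rn)) {
    sel <- ii == i
    if (any(sel))
      dest[sel] <- sample.int(N_REGIONS, sum(sel), replace = TRUE,
                              prob = truth@psi[i, ])
  }

  # harvest + reporting collapsed into one Bernoulli per bird
  p_rec <- truth@lambda[band_type] * truth@h
  recovered <- stats::runif(n) < p_rec

  recovery_date <- rep(as.Date(NA), n)
  recovery_region <- rep(NA_character_, n)
  nr <- sum(recovered)
  if (nr > 0) {
    season <- year[recovered] + sample.int(3L, nr, replace = TRUE)
    month <- sample(c(10L, 11L, 12L, 1L, 2L), nr, replace = TRUE)
    day <- sample.int(28L, nr, replace = TRUE)
    cal_year <- ifelse(month >= 10L, season, season + 1L)
    recovery_date[recovered] <- as.Date(sprintf("%d-%02d-%02d",
                                                cal_year, month, day))
    recovery_region[recovered] <- rn[dest[recovered]]
  }

  records <- data.frame(
    band_id = sprintf("B%07d", seq_len(n)),
    band_type = band_type, banding_date = banding_date,
    banding_region = region_i, recovery_date = recovery_date,
    recovery_region = recovery_region, stringsAsFactors = FALSE
  )

  # exact recovery ledger per band type
  types <- sort(unique(co$band_type))
  ledgerD <- lapply(types, function(k) {
    sel <- recovered & band_type == k
    D <- table(factor(region_i[sel], levels = rn),
               factor(rn[dest[sel]], levels = rn))
    matrix(as.integer(D), N_REGIONS, N_REGIONS, dimnames = list(rn, rn))
  })
  names(ledgerD) <- types
  planted <- c(not_preseason = 0L, not_hunting_season = 0L,
               direct_same_region = 0L)

  if (filter_noise) {
    n_plant <- max(5L, round(0.001 * n))
    yrs <- sort(unique(year))
    plantOne <- function(tag, band_md, rec_md, same_region, rec_offset) {
      y <- sample(yrs, n_plant, replace = TRUE)
      reg <- sample(rn, n_plant, replace = TRUE)
      rreg <- if (same_region) reg else sample(rn, n_plant, replace = TRUE)
      data.frame(
        band_id = sprintf("X%s%05d", tag, seq_len(n_plant)),
        band_type = sample(types, n_plant, replace = TRUE),
        banding_date = as.Date(paste0(y, "-", band_md)),
        banding_region = reg,
        recovery_date = as.Date(paste0(y + rec_offset, "-", rec_md)),
        recovery_region = rreg, stringsAsFactors = FALSE
      )
    }
    noise <- rbind(
      plantOne("A", "06-15", "11-10", FALSE, 1L),  # banded outside preseason
      plantOne("C", "08-10", "03-15", FALSE, 1L),  # recovered outside Oct-Feb
      plantOne("D", "08-10", "11-10", TRUE, 0L)    # direct same-region
    )
    records <- rbind(records, noise)
    planted <- c(not_preseason = n_plant, not_hunting_season = n_plant,
                 direct_same_region = n_plant)
  }
  rownames(records) <- NULL
  list(records = records,
       ledger = list(D = ledgerD, n_unrecovered = n - nr,
                     planted = planted))
}

#' Continental-scale black duck scenario
#'
#' A built-in synthetic scenario emulating six decades of preseason
#' black duck banding across the seven-region range, for end-to-end
#' demonstrations and parameter-recovery tests. Its true movement
#' matrix encodes the qualitative continental pattern: strong flyway
#' fidelity, most breeding-region birds moving to a wintering region
#' (with western breeders wintering in the Interior and eastern
#' breeders on the Atlantic coast), very small stay probabilities for
#' the northern breeding regions, and modest northward movement out of
#' every wintering region. Three band types with distinct reporting
#' probabilities are included: `mail_in` (0.32), `web` (0.70) and
#' `reward` (0.98 — reward bands are reported nearly always). Harvest
#' rate is 0.055 (the continental mean reported by harvest-rate
#' syntheses). Cohorts cover banding years 1951-2008 (recoveries
#' through 2011), sized so the expected number of reported recoveries
#' is about 15,000.
#'
#' @param seed simulation seed stored in the returned truth.
#' @return A [SyntheticTruth-class].
#' @examples
#' truth <- blackDuckScenario()
#' expectedRecoveries(truth)
#' @export
blackDuckScenario <- function(seed = 1L) {
  rn <- regionNames()
  psi <- matrix(c(
    # NW     SW     NE     SE    NAtl   SAtl    Int
    0.033, 0.010, 0.007, 0.050, 0.050, 0.150, 0.700,  # NW Canada
    0.005, 0.002, 0.008, 0.085, 0.050, 0.250, 0.600,  # SW Canada
    0.008, 0.010, 0.012, 0.390, 0.290, 0.210, 0.080,  # NE Canada
    0.010, 0.015, 0.040, 0.135, 0.350, 0.380, 0.070,  # SE Canada
    0.016, 0.020, 0.050, 0.150, 0.294, 0.420, 0.050,  # N Atlantic
    0.020, 0.020, 0.040, 0.120, 0.180, 0.550, 0.070,  # S Atlantic
    0.040, 0.060, 0.020, 0.060, 0.030, 0.270, 0.520   # Interior
  ), nrow = 7, byrow = TRUE, dimnames = list(rn, rn))

  lambda <- c(mail_in = 0.32, web = 0.70, reward = 0.98)
  totals <- c(mail_in = 700000, web = 50000, reward = 14000)
  region_prop <- stats::setNames(
    c(0.06, 0.04, 0.22, 0.30, 0.14, 0.10, 0.14), rn)
  years <- 1951:2008
  cohorts <- expand.grid(band_type = names(totals), region = rn,
                         year = years, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  cohorts$n <- round(totals[cohorts$band_type] *
                       region_prop[cohorts$region] / length(years))
  syntheticTruth(psi, lambda, h = 0.055, cohorts = cohorts, seed = seed)
}
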