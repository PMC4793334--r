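# fixtures are built in code at test time; nothing binary on disk

# a minimal valid record table
makeRecords <- function(band_id = c("a1", "a2"),
                        band_type = "mail_in",
                        banding_date = as.Date("1960-08-15"),
                        banding_region = "NE Canada",
                        recovery_date = as.Date("1960-11-02"),
                        recovery_region = c("NE Canada", "S Atlantic")) {
  data.frame(band_id = band_id, band_type = band_type,
             banding_date = banding_date, banding_region = banding_region,
             recovery_date = recovery_date,
             recovery_region = recovery_region, stringsAsFactors = FALSE)
}

# CSV fixture with a known number of deliberately corrupted rows
writeCorruptedFixture <- function(path, n_good = 115, n_bad = 5, seed = 404) {
  set.seed(seed)
  rn <- bandmove::regionNames()
  yrs <- sample(1955:2005, n_good + n_bad, replace = TRUE)
  df <- data.frame(
    band_id = sprintf("F%04d", seq_len(n_good + n_bad)),
    band_type = sample(c("mail_in", "web"), n_good + n_bad, TRUE),
    banding_date = sprintf("%d-08-%02d", yrs, sample(28, n_good + n_bad, TRUE)),
    banding_region = sample(rn, n_good + n_bad, TRUE),
    recovery_date = sprintf("%d-11-%02d", yrs + 1, sample(28, n_good + n_bad, TRUE)),
    recovery_region = sample(rn, n_good + n_bad, TRUE),
    stringsAsFactors = FALSE
  )
  bad <- seq(n_good + 1, n_good + n_bad)
  df$banding_date[bad[1]] <- "not-a-date"
  df$banding_region[bad[2]] <- "Atlantis"
  df$recovery_region[bad[3]] <- ""          # recovery date without region
  df$recovery_date[bad[4]] <- "1900-13-45"  # unparseable -> orphan region
  df$recovery_date[bad[5]] <- sprintf("%d-11-01", yrs[bad[5]] - 2)  # before banding
  df <- df[sample(nrow(df)), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# a degenerate PosteriorSummary whose posterior is a point mass at psi
makePointSummary <- function(psi) {
  rn <- rownames(psi)
  if (is.null(rn)) {
    rn <- bandmove::regionNames()
    dimnames(psi) <- list(rn, rn)
  }
  flat <- matrix(as.vector(t(psi)), nrow = 1)
  methods::new("PosteriorSummary",
               mean = psi, sd = psi * 0, ciLow = psi, ciHigh = psi,
               weights = c(all = 1), draws = flat, drawWeights = 1,
               regions = rn)
}

# batch-means Monte-Carlo standard error of a [draw, chain] matrix
mcseDraws <- function(x2, nbatch = 25L) {
  n <- nrow(x2)
  b <- n %/% nbatch
  bm <- c(apply(x2, 2, function(v) colMeans(matrix(v[seq_len(b * nbatch)], b))))
  stats::sd(bm) / sqrt(length(bm))
}

# empty 7x7 recovery matrix for prior-only runs
emptyRecoveryMatrix <- function(band_type = "toy") {
  rn <- bandmove::regionNames()
  D0 <- matrix(0L, 7, 7, dimnames = list(rn, rn))
  bandmove::recoveryMatrix(band_type, D0, rep(0L, 7))
}

# small single-band-type truth over the canonical regions
smallTruth <- function(n_per_region = 2000, lambda = 0.7, h = 0.055,
                       seed = 1, band_type = "web", year = 1990) {
  rn <- bandmove::regionNames()
  bandmove::syntheticTruth(
    bandmove::truePsi(bandmove::blackDuckScenario()),
    stats::setNames(lambda, band_type), h = h,
    cohorts = data.frame(band_type = band_type, region = rn,
                         year = year, n = n_per_region),
    seed = seed)
}
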