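test_that("seasonOf labels hunting seasons by their start year", {
  d <- as.Date(c("1971-01-15", "1970-11-30", "1970-08-01", "1971-02-28",
                 "1970-10-01"))
  expect_equal(seasonOf(d), c(1970L, 1970L, NA, 1970L, 1970L))
})

test_that("direct same-region recoveries are removed, cross-region kept", {
  # banded 1960-08-15 NE Canada, recovered 1960-11-02: dropped only when
  # the recovery is in the banding region
  recs <- makeRecords()   # rows: NE Canada -> NE Canada, NE Canada -> S Atlantic
  out <- filterRecords(recs)
  expect_equal(nrow(out$kept), 1)
  expect_equal(out$kept$recovery_region, "S Atlantic")
  expect_equal(unname(out$audit["direct_same_region"]), 1L)
  # a January direct recovery belongs to the preceding season: still direct
  jan <- makeRecords(band_id = "j1",
                     recovery_date = as.Date("1961-01-20"),
                     recovery_region = "NE Canada")[1, ]
  expect_equal(nrow(filterRecords(jan)$kept), 0)
  # same-region recovery one season later is legitimate site fidelity
  later <- makeRecords(band_id = "l1",
                       recovery_date = as.Date("1961-11-02"),
                       recovery_region = "NE Canada")[1, ]
  expect_equal(nrow(filterRecords(later)$kept), 1)
})

test_that("out-of-preseason bandings and out-of-season recoveries drop", {
  recs <- rbind(
    makeRecords(band_id = "p1", banding_date = as.Date("1960-06-20"),
                recovery_region = "S Atlantic")[1, ],
    makeRecords(band_id = "p2", recovery_date = as.Date("1961-04-10"),
                recovery_region = "S Atlantic")[1, ],
    makeRecords(band_id = "p3", recovery_date = as.Date(NA),
                recovery_region = NA)[1, ])
  out <- filterRecords(recs)
  expect_equal(nrow(out$kept), 0)
  expect_equal(unname(out$audit[c("not_preseason", "no_recovery",
                                  "not_hunting_season")]),
               c(1L, 1L, 1L))
})

test_that("audit counts equal the counts planted by the simulator", {
  truth <- smallTruth(n_per_region = 1500, seed = 21)
  sim <- simulateDataset(truth, filter_noise = TRUE)
  out <- filterRecords(sim$records)
  expect_equal(unname(out$audit["not_preseason"]),
               unname(sim$ledger$planted["not_preseason"]))
  expect_equal(unname(out$audit["not_hunting_season"]),
               unname(sim$ledger$planted["not_hunting_season"]))
  expect_equal(unname(out$audit["direct_same_region"]),
               unname(sim$ledger$planted["direct_same_region"]))
  expect_equal(unname(out$audit["no_recovery"]), sim$ledger$n_unrecovered)
})

test_that("filtering is idempotent and order-invariant", {
  truth <- smallTruth(n_per_region = 800, seed = 13)
  sim <- simulateDataset(truth, filter_noise = TRUE)
  once <- filterRecords(sim$records)
  twice <- filterRecords(once$kept)
  expect_equal(twice$kept, once$kept)
  expect_equal(sum(twice$audit), 0L)
  set.seed(99)
  shuf <- sim$records[sample(nrow(sim$records)), ]
  reshuf <- filterRecords(shuf)
  expect_equal(reshuf$audit, once$audit)
  expect_equal(
    reshuf$kept[order(reshuf$kept$band_id), "band_id"],
    once$kept[order(once$kept$band_id), "band_id"])
})

test_that("recovery matrices count filtered records cell by cell", {
  recs <- makeRecords(
    band_id = c("a", "b", "c"), band_type = "legacy",
    recovery_region = c("SE Canada", "SE Canada", "N Atlantic"))
  totals <- data.frame(band_type = "legacy", region = "NE Canada",
                       n_banded = 100)
  mats <- buildRecoveryMatrices(recs, totals)
  expect_named(mats, "legacy")
  D <- recoveryCounts(mats$legacy)
  expect_equal(D["NE Canada", "SE Canada"], 2L)
  expect_equal(D["NE Canada", "N Atlantic"], 1L)
  expect_equal(sum(D), 3L)
  expect_equal(unname(bandedTotals(mats$legacy)["NE Canada"]), 100L)
  # no matrix for band types without records
  expect_false("reward" %in% names(mats))
})

test_that("recoveries exceeding banded totals are an error", {
  recs <- makeRecords(band_id = c("a", "b"),
                      recovery_region = "S Atlantic")
  totals <- data.frame(band_type = "mail_in", region = "NE Canada",
                       n_banded = 1)
  expect_error(buildRecoveryMatrices(recs, totals), "inconsistent")
})

test_that("kept records are conserved into matrix counts", {
  truth <- blackDuckScenario(seed = 5)
  truth@cohorts <- truth@cohorts[truth@cohorts$year %in% 1980, ]
  sim <- simulateDataset(truth)
  out <- filterRecords(sim$records)
  mats <- buildRecoveryMatrices(out$kept, tallyBandedTotals(sim$records))
  expect_equal(sum(vapply(mats, function(m) sum(recoveryCounts(m)), 0)),
               nrow(out$kept))
  # permutation invariance of the counts
  set.seed(7)
  shuf <- out$kept[sample(nrow(out$kept)), ]
  mats2 <- buildRecoveryMatrices(shuf, tallyBandedTotals(sim$records))
  expect_equal(lapply(mats2, recoveryCounts), lapply(mats, recoveryCounts))
})
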