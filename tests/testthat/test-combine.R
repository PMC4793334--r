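makeDrawsFromPsi <- function(psi_list, band_type, jitter = 0, seed = 1) {
  # PosteriorDraws whose draws are the given matrices (optionally
  # jittered on the simplex), split over 2 chains
  set.seed(seed)
  rn <- regionNames()
  flat <- t(vapply(psi_list, function(p) as.vector(t(p)), numeric(49)))
  n <- nrow(flat)
  arr <- array(0, c(n, 2, 49))
  arr[, 1, ] <- flat
  arr[, 2, ] <- flat
  methods::new("PosteriorDraws", bandType = band_type, psi = arr,
               lambda = matrix(0.5, n, 2), h = matrix(0.05, n, 2),
               regions = rn, acceptance = c(psi_rows = 1),
               rhat = NA_real_, converged = TRUE)
}

test_that("band-type weights are recovery proportions", {
  rn <- regionNames()
  D1 <- matrix(0L, 7, 7, dimnames = list(rn, rn)); D1[1, 5] <- 300L
  D2 <- matrix(0L, 7, 7, dimnames = list(rn, rn)); D2[2, 6] <- 100L
  m1 <- recoveryMatrix("a", D1, rep(1000L, 7))
  m2 <- recoveryMatrix("b", D2, rep(3000L, 7))
  w <- bandTypeWeights(list(m1, m2))
  expect_equal(w, c(a = 0.75, b = 0.25))
  expect_equal(bandTypeWeights(list(m1)), c(a = 1))
  # sensitivity mode: weight by bandings instead
  wb <- bandTypeWeights(list(m1, m2), weight_by = "bandings")
  expect_equal(wb, c(a = 0.25, b = 0.75))
  m0 <- recoveryMatrix("z", D1 * 0L, rep(10L, 7))
  expect_error(bandTypeWeights(list(m0)), "zero total")
})

test_that("weights equal the simulator's planted recovery proportions", {
  truth <- blackDuckScenario(seed = 2)
  truth@cohorts <- truth@cohorts[truth@cohorts$year %in% 1979:1981, ]
  sim <- simulateDataset(truth)
  mats <- buildRecoveryMatrices(filterRecords(sim$records)$kept,
                                tallyBandedTotals(sim$records))
  w <- bandTypeWeights(mats)
  planted <- vapply(sim$ledger$D, sum, 0)[names(w)]
  expect_equal(w, planted / sum(planted))
})

test_that("combining identical posteriors reproduces either one", {
  psi <- truePsi(blackDuckScenario())
  d1 <- makeDrawsFromPsi(list(psi, psi), "a")
  d2 <- makeDrawsFromPsi(list(psi, psi), "b")
  s <- combinePosteriors(list(d1, d2), c(a = 0.4, b = 0.6))
  expect_equal(psiMeans(s), psi, tolerance = 1e-12)
  expect_equal(max(psiSds(s)), 0, tolerance = 1e-12)
})

test_that("a zero weight removes a band type's influence entirely", {
  psiA <- truePsi(blackDuckScenario())
  psiB <- matrix(1 / 7, 7, 7)
  dA <- makeDrawsFromPsi(list(psiA), "a")
  dB <- makeDrawsFromPsi(list(psiB), "b")
  s <- combinePosteriors(list(dA, dB), c(a = 1, b = 0))
  expect_equal(psiMeans(s), psiA, tolerance = 1e-12)
})

test_that("mixture mean is the weighted average of planted matrices", {
  psiA <- truePsi(blackDuckScenario())
  psiB <- matrix(1 / 7, 7, 7, dimnames = dimnames(psiA))
  dA <- makeDrawsFromPsi(list(psiA), "a")
  dB <- makeDrawsFromPsi(list(psiB), "b")
  s <- combinePosteriors(list(dA, dB), c(a = 0.6, b = 0.4))
  expect_equal(psiMeans(s), 0.6 * psiA + 0.4 * psiB, tolerance = 1e-12)
  # weighted mean preserves row-stochasticity
  expect_equal(unname(rowSums(psiMeans(s))), rep(1, 7), tolerance = 1e-9)
  # weights must match band types
  expect_error(combinePosteriors(list(dA, dB), c(a = 0.6, z = 0.4)),
               "cover exactly")
})

test_that("unequal chain lengths do not distort mixture weights", {
  psiA <- truePsi(blackDuckScenario())
  psiB <- matrix(1 / 7, 7, 7)
  dA <- makeDrawsFromPsi(rep(list(psiA), 50), "a")   # 100 draws
  dB <- makeDrawsFromPsi(rep(list(psiB), 5), "b")    # 10 draws
  s <- combinePosteriors(list(dA, dB), c(a = 0.5, b = 0.5))
  expect_equal(psiMeans(s), 0.5 * psiA + 0.5 * psiB, tolerance = 1e-12)
})

test_that("derived summaries match closed forms for identity and uniform", {
  s_id <- makePointSummary(diag(7))
  d_id <- derivedSummaries(s_id)
  expect_equal(d_id$stay, rep(1, 7))
  expect_equal(d_id$to_wintering[d_id$role == "wintering"], rep(1, 3))
  expect_equal(d_id$to_wintering[d_id$role == "breeding"], rep(0, 4))
  expect_equal(d_id$northward, rep(0, 7))
  s_u <- makePointSummary(matrix(1 / 7, 7, 7))
  d_u <- derivedSummaries(s_u)
  expect_equal(d_u$to_wintering, rep(3 / 7, 7))
  expect_equal(d_u$stay, rep(1 / 7, 7))
})

test_that("derived summaries equal hand-computed sums on a planted matrix", {
  psi <- truePsi(blackDuckScenario())
  d <- derivedSummaries(makePointSummary(psi))
  reg <- regionRegistry()
  wcols <- reg$region[reg$role == "wintering"]
  for (i in seq_len(7)) {
    r <- reg$region[i]
    expect_equal(d$stay[i], psi[r, r])
    expect_equal(d$to_wintering[i], sum(psi[r, wcols]))
    north <- reg$region[reg$north_rank > reg$north_rank[i]]
    expect_equal(d$northward[i], sum(psi[r, north]))
  }
  # stay + elsewhere partitions each row
  expect_equal(d$stay + sapply(seq_len(7), function(i)
    sum(psi[i, -i])), rep(1, 7))
})

test_that("a custom north ordering overrides the registry", {
  psi <- truePsi(blackDuckScenario())
  rn <- regionNames()
  flat_rank <- setNames(rep(1L, 7), rn)   # nothing is north of anything
  d <- derivedSummaries(makePointSummary(psi), north_rank = flat_rank)
  expect_equal(d$northward, rep(0, 7))
})
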