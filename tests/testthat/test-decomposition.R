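test_that("the switching ensemble enumerates all 24 distinct orderings", {
  ords <- factorOrderings()
  expect_equal(nrow(ords), 24)
  expect_equal(ncol(ords), 4)
  expect_equal(anyDuplicated(apply(ords, 1, paste, collapse = "-")), 0L)
  expect_true(all(apply(ords, 1, function(r)
    setequal(r, c("P", "AF", "MR", "PAF")))))
})

test_that("identical states decompose to zero; a lone factor carries the whole change", {
  crfs <- defaultCRFParameters()
  set.seed(21)
  s0 <- randomFactorState(2000)
  same <- decomposePair(s0, s0, crfs)
  expect_equal(unname(as.vector(same)), rep(0, 8))
  # only population changes: its contribution is the full difference
  s1 <- s0
  s1$year <- 2001
  s1$P <- s0$P * c(1.1, 0.9)
  dp <- decomposePair(s0, s1, crfs)
  tot <- attr(dp, "total")
  expect_equal(dp[, "P"], tot[, "end"] - tot[, "start"], tolerance = 1e-12)
  expect_equal(unname(dp[, "AF"]), c(0, 0))
  expect_equal(unname(dp[, "MR"]), c(0, 0))
  expect_equal(unname(dp[, "PAF"]), c(0, 0))
})

test_that("factor contributions conserve the total change on random instances", {
  crfs <- defaultCRFParameters()
  set.seed(31)
  for (i in 1:20) {
    s0 <- randomFactorState(2000)
    s1 <- randomFactorState(2001)
    s1$AF <- s1$AF[, ]  # same support
    dp <- decomposePair(s0, s1, crfs)
    tot <- attr(dp, "total")
    expect_equal(rowSums(dp), tot[, "end"] - tot[, "start"],
                 tolerance = 1e-9)
  }
})

test_that("the ensemble mean equals brute-force Shapley values", {
  crfs <- defaultCRFParameters()
  set.seed(41)
  for (i in 1:5) {
    s0 <- randomFactorState(2000)
    s1 <- randomFactorState(2001)
    dp <- decomposePair(s0, s1, crfs)
    sh <- shapleyOracle(s0, s1, crfs)
    expect_equal(colSums(dp), sh, tolerance = 1e-9)
  }
})

test_that("the ensemble mean is invariant to relabelling the factors (symmetry)", {
  crfs <- defaultCRFParameters()
  set.seed(51)
  s0 <- randomFactorState(2000)
  s1 <- randomFactorState(2001)
  dp <- decomposePair(s0, s1, crfs)
  # recompute with the roles of the two states swapped: contributions negate
  rev <- decomposePair(s1, s0, crfs)
  expect_equal(dp, -rev[, colnames(dp)], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("chained series ledgers telescope and are zero at the pivot", {
  crfs <- defaultCRFParameters()
  cfg <- smallConfig()
  idx <- territoryLayout(cfg)
  dem <- generateDemography(cfg)
  es <- exposureSeries(generateExposureRasters(cfg, idx),
                       generatePopulationRasters(cfg, idx), idx)
  states <- factorStates(dem$population, dem$deaths,
                         es[es$scope_type == "territory", ])
  led <- decomposeSeries(states, crfs, pivotYear = 2004)
  base <- attr(led, "baseline")
  atPivot <- led[led$year == 2004, ]
  expect_equal(atPivot$cumulative, rep(0, nrow(atPivot)))
  expect_equal(atPivot$net, rep(0, nrow(atPivot)))
  for (y in c(1999, 2001, 2007, 2009)) for (tk in c("T01", "T03")) {
    sub <- led[led$year == y & led$scope == tk, ]
    net <- base$value[base$year == y & base$scope == tk] -
      base$value[base$year == 2004 & base$scope == tk]
    expect_equal(sum(sub$cumulative), net, tolerance = 1e-9)
    expect_equal(unique(sub$net), net, tolerance = 1e-9)
  }
  expect_error(decomposeSeries(states, crfs, pivotYear = 1901),
               "outside")
})

test_that("constant states produce an identically zero ledger", {
  crfs <- defaultCRFParameters()
  set.seed(61)
  s <- randomFactorState(2000)
  states <- lapply(0:5, function(i) { s2 <- s; s2$year <- 2000 + i; s2 })
  led <- decomposeSeries(states, crfs, pivotYear = 2003)
  expect_equal(led$cumulative, rep(0, nrow(led)))
  expect_equal(max(abs(led$delta), na.rm = TRUE), 0)
})

test_that("an exposure-only scenario attributes the entire change to the PAF factor", {
  crfs <- defaultCRFParameters()
  set.seed(71)
  s <- randomFactorState(2000)
  states <- lapply(0:4, function(i) {
    s2 <- s
    s2$year <- 2000 + i
    s2$E <- s$E * 0.9^i  # declining exposure, everything else frozen
    s2
  })
  led <- decomposeSeries(states, crfs, pivotYear = 2000)
  others <- led[led$factor != "PAF", ]
  expect_equal(max(abs(others$cumulative)), 0)
  pafrows <- led[led$factor == "PAF", ]
  expect_equal(pafrows$cumulative, pafrows$net, tolerance = 1e-12)
  expect_lte(max(pafrows$net), 0)
})

test_that("chaining agrees with an endpoint decomposition when one factor moves linearly", {
  crfs <- defaultCRFParameters()
  set.seed(81)
  s <- randomFactorState(2000)
  states <- lapply(0:4, function(i) {
    s2 <- s
    s2$year <- 2000 + i
    s2$P <- s$P * (1 + 0.05 * i)
    s2
  })
  led <- decomposeSeries(states, crfs, pivotYear = 2000)
  endpoint <- decomposePair(states[[1]], states[[5]], crfs)
  chainP <- led$cumulative[led$factor == "P" & led$year == 2004]
  expect_equal(chainP, unname(endpoint[, "P"]), tolerance = 1e-9)
})

test_that("sensitivity-mode ledgers decompose the marginal benefit and normalize to the pivot", {
  crfs <- defaultCRFParameters()
  cfg <- smallConfig()
  idx <- territoryLayout(cfg)
  dem <- generateDemography(cfg)
  es <- exposureSeries(generateExposureRasters(cfg, idx),
                       generatePopulationRasters(cfg, idx), idx)
  terr <- es[es$scope_type == "territory", ]
  states <- factorStates(dem$population, dem$deaths, terr)
  sled <- decomposeSensitivitySeries(states, crfs, pivotYear = 2004)
  base <- attr(sled, "baseline")
  # the baseline of the sensitivity ledger is dD/dE itself
  mb <- marginalBenefit(dem$deaths, terr, dem$population, crfs)
  key <- paste(mb$scope, mb$year)
  expect_equal(base$value[match(key, paste(base$scope, base$year))],
               mb$dDdE, tolerance = 1e-9)
  glob <- aggregateLedger(sled, idx, "global", normalize = TRUE)
  gbase <- attr(glob, "baseline")
  pivotVal <- gbase$value[gbase$year == 2004]
  sub <- glob[glob$year == 2009, ]
  expect_equal(sum(sub$cumulative) * pivotVal,
               gbase$value[gbase$year == 2009] - pivotVal,
               tolerance = 1e-9 * pivotVal)
})

test_that("factor states reconstruct the deaths table exactly", {
  cfg <- smallConfig()
  idx <- territoryLayout(cfg)
  dem <- generateDemography(cfg)
  es <- exposureSeries(generateExposureRasters(cfg, idx),
                       generatePopulationRasters(cfg, idx), idx)
  states <- factorStates(dem$population, dem$deaths,
                         es[es$scope_type == "territory", ])
  s <- states[["2002"]]
  expect_equal(unname(colSums(s$AF)), rep(1, length(s$territories)))
  dth <- dem$deaths[dem$deaths$year == 2002, ]
  recon <- vapply(seq_len(nrow(dth)), function(r) {
    k <- match(dth$territory[r], s$territories)
    i <- match(dth$age[r], 0:95)
    j <- match(dth$disease[r], allDiseases)
    s$P[k] * s$AF[i, k] * s$MR[i, j, k]
  }, numeric(1))
  expect_equal(recon, dth$deaths, tolerance = 1e-9)
})
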