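test_that("noiseless exposure rasters follow the configured trajectory exactly", {
  cfg <- scenarioConfig(nTerritories = 1L, nRegions = 1L,
                        gridShape = c(6L, 6L), years = 1998:2000,
                        breakpointYear = 1999L, baseExposure = 20,
                        preTrend = 1, postTrend = 1, noiseSd = 0)
  pm <- generateExposureRasters(cfg)
  means <- vapply(pm, function(r) mean(gridValues(r)), numeric(1))
  expect_equal(unname(means), c(20, 21, 22))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- smallConfig()
  a <- generateExposureRasters(cfg)
  b <- generateExposureRasters(cfg)
  expect_identical(lapply(a, gridValues), lapply(b, gridValues))
  pa <- generatePopulationRaster(cfg, 2003)
  pb <- generatePopulationRaster(cfg, 2003)
  expect_identical(gridValues(pa), gridValues(pb))
  expect_identical(generateDemography(cfg), generateDemography(cfg))
})

test_that("piecewise trends around the breakpoint are recovered by OLS", {
  cfg <- smallConfig(years = 1998:2019, breakpointYear = 2011L,
                     preTrend = 0.8, postTrend = -0.5, noiseSd = 1)
  idx <- territoryLayout(cfg)
  pm <- generateExposureRasters(cfg, idx)
  pop <- generatePopulationRasters(cfg, idx)
  es <- exposureSeries(pm, pop, idx)
  # a 2-SE band is a ~95% check per fit, so demand near-universal (not
  # universal) success across the territory x period fits, and universal
  # success at 4 SE
  within2 <- 0L; fits <- 0L
  for (tk in territoryNames(idx)) {
    s <- es[es$scope == tk, ]
    pre <- olsTrend(s$year[s$year <= 2011], s$E[s$year <= 2011])
    post <- olsTrend(s$year[s$year >= 2011], s$E[s$year >= 2011])
    sePre <- (pre$ci95_high - pre$ci95_low) / 2 / qt(0.975, pre$n_years - 2)
    sePost <- (post$ci95_high - post$ci95_low) / 2 /
      qt(0.975, post$n_years - 2)
    within2 <- within2 + (abs(pre$slope - 0.8) < 2 * sePre) +
      (abs(post$slope + 0.5) < 2 * sePost)
    fits <- fits + 2L
    expect_lt(abs(pre$slope - 0.8), 4 * sePre)
    expect_lt(abs(post$slope + 0.5), 4 * sePost)
  }
  expect_gte(within2, fits - 1L)
})

test_that("the noiseless reversal scenario peaks exactly at the breakpoint", {
  cfg <- smallConfig(years = 1998:2019, breakpointYear = 2011L,
                     preTrend = 0.8, postTrend = -0.5, noiseSd = 0)
  idx <- territoryLayout(cfg)
  es <- exposureSeries(generateExposureRasters(cfg, idx),
                       generatePopulationRasters(cfg, idx), idx)
  g <- es[es$scope_type == "global", ]
  expect_equal(g$year[which.max(g$E)], 2011)
  expect_true(all(diff(g$E[g$year <= 2011]) > 0))
  expect_true(all(diff(g$E[g$year >= 2011]) < 0))
})

test_that("population rasters compound at the configured growth rate", {
  cfg0 <- smallConfig(popGrowthRate = 0)
  idx <- territoryLayout(cfg0)
  t0 <- sum(gridValues(generatePopulationRaster(cfg0, 1998, idx)))
  t5 <- sum(gridValues(generatePopulationRaster(cfg0, 2003, idx)))
  expect_equal(t0, t5)
  cfg2 <- smallConfig(popGrowthRate = 0.02, years = 1998:2008)
  idx2 <- territoryLayout(cfg2)
  a <- sum(gridValues(generatePopulationRaster(cfg2, 1998, idx2)))
  b <- sum(gridValues(generatePopulationRaster(cfg2, 2008, idx2)))
  expect_equal(b, a * 1.02^10, tolerance = 1e-10)
  expect_error(generatePopulationRaster(cfg2, 2020, idx2), "outside")
})

test_that("demography honours aging, mortality decline and eligibility rules", {
  cfg <- smallConfig(agingRate = 0, mortalityDeclineRate = 0)
  dem <- generateDemography(cfg)
  m98 <- meanAge(dem$population, "T01", 1998)
  m05 <- meanAge(dem$population, "T01", 2005)
  expect_equal(m98, m05, tolerance = 1e-8)
  mr98 <- mortalityRate(dem$deaths, dem$population, "T01", 1998)
  mr05 <- mortalityRate(dem$deaths, dem$population, "T01", 2005)
  expect_equal(mr98, mr05, tolerance = 1e-8)
  # no stroke deaths outside the adult ages, by construction
  stroke <- dem$deaths[dem$deaths$disease == "Stroke", ]
  expect_true(all(stroke$age >= 25))
  lri <- dem$deaths[dem$deaths$disease == "LRI", ]
  expect_true(all(lri$age < 5 | lri$age >= 25))
  expect_silent(validateDeathsTable(dem$deaths))
})

test_that("the configured mean-age drift is recovered from the tables", {
  cfg <- smallConfig(agingRate = 0.2, baseMeanAge = 28)
  dem <- generateDemography(cfg)
  for (y in c(1998, 2004, 2009)) {
    expect_equal(meanAge(dem$population, "T02", y),
                 28 + 0.2 * (y - 1998), tolerance = 1e-6)
  }
})

test_that("built-in CRF set is age-resolved where it should be and normalized", {
  crfs <- defaultCRFParameters()
  young <- crfFor(crfs, "IHD", 27)
  old <- crfFor(crfs, "IHD", 82)
  expect_false(isTRUE(all.equal(young@theta, old@theta)))
  expect_identical(crfFor(crfs, "COPD", 30), crfFor(crfs, "COPD", 90))
  for (s in crfs) {
    expect_equal(gemmRR(s, s@zCf), 1)
    expect_equal(gemmRR(s, 0), 1)
    rrs <- vapply(c("lower", "central", "upper"),
                  function(v) gemmRR(s, 50, v), numeric(1))
    expect_true(rrs[1] <= rrs[2] && rrs[2] <= rrs[3])
    expect_true(all(diff(gemmRR(s, seq(0, 120, by = 2))) >= 0))
  }
  # LRI covers children, the others do not
  expect_s4_class(crfFor(crfs, "LRI", 2), "CRFSpec")
  expect_error(crfFor(crfs, "DM", 2), "no concentration-response")
})

test_that("scenario configs validate their invariants and survive YAML", {
  expect_error(scenarioConfig(years = 1998:1999), "at least 3 years")
  expect_error(scenarioConfig(breakpointYear = 1998L), "strictly inside")
  expect_error(scenarioConfig(baseExposure = -1), "positive")
  expect_error(scenarioConfig(nTerritories = 300L,
                              gridShape = c(10L, 10L)), "at least one cell")
  cfg <- smallConfig()
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeScenarioConfig(cfg, f)
  back <- readScenarioConfig(f)
  expect_equal(back@years, cfg@years)
  expect_equal(back@baseExposure, cfg@baseExposure, tolerance = 1e-9)
  expect_equal(back@seed, cfg@seed)
  expect_equal(back@noiseSd, cfg@noiseSd)
})
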