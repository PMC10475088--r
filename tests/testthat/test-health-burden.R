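test_that("GEMM relative risk obeys its closed form and normalization", {
  crf <- crfSpec("COPD", 25, Inf, theta = 0.16, alpha = 6.5, mu = 2.5,
                 nu = 32, zCf = 2.4)
  # independent scalar evaluation of the closed form at E = 50
  z <- 50 - 2.4
  expected <- exp(0.16 * log(1 + z / 6.5) / (1 + exp(-(z - 2.5) / 32)))
  expect_equal(gemmRR(crf, 50), expected, tolerance = 1e-14)
  expect_equal(gemmRR(crf, 2.4), 1)
  expect_equal(gemmRR(crf, 1), 1)  # below the counterfactual
  flat <- crfSpec("COPD", 25, Inf, theta = 0, alpha = 6.5, mu = 2.5,
                  nu = 32)
  expect_equal(gemmRR(flat, c(0, 10, 80)), rep(1, 3))
  expect_error(gemmRR(crf, -1), "non-negative")
  expect_error(crfSpec("COPD", 25, Inf, theta = 0.1, alpha = -1,
                       mu = 0, nu = 1), "positive")
})

test_that("attributable fractions follow 1 - 1/RR", {
  crf <- crfSpec("LC", 25, Inf, theta = 0.15, alpha = 6.2, mu = 9.3,
                 nu = 29.8)
  expect_equal(paf(crf, crf@zCf), 0)
  rr <- gemmRR(crf, 40)
  expect_equal(paf(crf, 40), 1 - 1 / rr)
  # closed-form anchors: RR = 2 -> 0.5, RR = 1.25 -> 0.2
  expect_equal(1 - 1 / 2, 0.5)
  e2 <- uniroot(function(E) gemmRR(crf, E) - 1.25, c(2.4, 500))$root
  expect_equal(paf(crf, e2), 0.2, tolerance = 1e-6)
})

test_that("attributable deaths equal a brute-force enumeration on a toy table", {
  crfs <- defaultCRFParameters()
  deaths <- expand.grid(territory = c("X", "Y"), year = 2000,
                        age = c(3L, 30L, 67L),
                        disease = c("IHD", "LRI"),
                        stringsAsFactors = FALSE)
  deaths <- deaths[mapply(eligibleCell, deaths$disease, deaths$age), ]
  deaths$deaths <- seq(100, by = 50, length.out = nrow(deaths))
  exposure <- data.frame(scope = c("X", "Y"), year = 2000,
                         E = c(25, 55))
  res <- attributableDeaths(deaths, exposure, crfs)
  EMap <- list("X 2000" = 25, "Y 2000" = 55)
  for (tk in c("X", "Y")) {
    sub <- deaths[deaths$territory == tk, ]
    for (v in c("central", "lower", "upper")) {
      expect_equal(res[[v]][res$scope == tk],
                   bruteForceBurden(sub, EMap, crfs, v),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(res$lower <= res$central & res$central <= res$upper))
  # single-cell sanity: D = 1000 at PAF 0.3 gives 300
  crfOne <- crfs[[which(vapply(crfs, function(s)
    s@disease == "COPD", logical(1)))[1]]]
  e03 <- uniroot(function(E) paf(crfOne, E) - 0.3, c(2.4, 2000))$root
  one <- data.frame(territory = "Z", year = 1999, age = 40L,
                    disease = "COPD", deaths = 1000)
  resOne <- attributableDeaths(one, data.frame(scope = "Z", year = 1999,
                                               E = e03), crfs)
  expect_equal(resOne$central, 300, tolerance = 1e-6)
})

test_that("zero excess exposure yields zero attributable deaths", {
  crfs <- defaultCRFParameters()
  deaths <- data.frame(territory = "X", year = 2000, age = c(30L, 70L),
                       disease = "IHD", deaths = c(500, 800))
  res <- attributableDeaths(deaths, data.frame(scope = "X", year = 2000,
                                               E = 2.4), crfs)
  expect_equal(res$central, 0)
  expect_equal(res$paf_a, 0)
})

test_that("overall PAF is the deaths-weighted mean and satisfies its identity", {
  crfs <- defaultCRFParameters()
  cfg <- smallConfig()
  idx <- territoryLayout(cfg)
  dem <- generateDemography(cfg)
  es <- exposureSeries(generateExposureRasters(cfg, idx),
                       generatePopulationRasters(cfg, idx), idx)
  terr <- es[es$scope_type == "territory", ]
  sub <- dem$deaths[dem$deaths$year == 2001, ]
  burden <- attributableDeaths(sub, terr, crfs)
  pafA <- overallPaf(sub, terr, crfs)
  expect_equal(pafA$paf_a * burden$deaths_total, burden$central,
               tolerance = 1e-12)
  expect_true(all(pafA$paf_a >= 0 & pafA$paf_a < 1))
  # uniform PAF across cells: overall PAF equals it (single curve, one E)
  uni <- data.frame(territory = "U", year = 2000,
                    age = c(30L, 50L, 80L), disease = "LC",
                    deaths = c(10, 400, 90))
  e <- data.frame(scope = "U", year = 2000, E = 47)
  crfLC <- crfFor(crfs, "LC", 50)
  expect_equal(overallPaf(uni, e, crfs)$paf_a, paf(crfLC, 47),
               tolerance = 1e-12)
})

test_that("attributable deaths are monotone in exposure and additive over regions", {
  crfs <- defaultCRFParameters()
  cfg <- smallConfig()
  idx <- territoryLayout(cfg)
  dem <- generateDemography(cfg)
  sub <- dem$deaths[dem$deaths$year %in% 1998:2000, ]
  demSub <- dem$population[dem$population$year %in% 1998:2000, ]
  terrs <- unique(sub$territory)
  eLow <- expand.grid(scope = terrs, year = 1998:2000)
  eLow$E <- 20; eHigh <- eLow; eHigh$E <- 45
  low <- attributableDeaths(sub, eLow, crfs, demSub)
  high <- attributableDeaths(sub, eHigh, crfs, demSub)
  expect_true(all(high$central >= low$central))
  reg <- aggregateBurden(low, idx, "region")
  regs <- territoryRegions(idx)
  for (r in unique(reg$scope)) for (y in 1998:2000) {
    members <- names(regs)[regs == r]
    expect_equal(reg$central[reg$scope == r & reg$year == y],
                 sum(low$central[low$scope %in% members & low$year == y]))
  }
  glob <- aggregateBurden(low, idx, "global")
  expect_equal(sum(glob$central), sum(low$central))
  expect_equal(glob$paf_a, glob$central / glob$deaths_total)
})

test_that("mortality rate and mean age reduce to their definitions", {
  dem <- data.frame(territory = "A", year = 2000, age = c(0L, 95L),
                    population = c(1000, 1000))
  expect_equal(meanAge(dem, "A"), 47.5)
  dem40 <- data.frame(territory = "A", year = 2000, age = 40L,
                      population = 5000)
  expect_equal(meanAge(dem40, "A"), 40)
  # uniform rate r: MR = r; doubling population halves MR
  pop <- data.frame(territory = "A", year = 2000, age = 30:34,
                    population = rep(200, 5))
  dth <- data.frame(territory = "A", year = 2000, age = 30:34,
                    disease = "IHD", deaths = rep(200 * 0.004, 5))
  expect_equal(mortalityRate(dth, pop, "A"), 0.004)
  pop2 <- pop; pop2$population <- 400
  expect_equal(mortalityRate(dth, pop2, "A"), 0.002)
  # toy pyramid against a hand-computed weighted mean
  pyr <- data.frame(territory = "B", year = 2000, age = c(10L, 20L, 30L),
                    population = c(3, 2, 1))
  expect_equal(meanAge(pyr, "B"), (30 + 40 + 30) / 6)
  expect_error(meanAge(pyr[0, ], "B"), "zero scope population")
  # relevant population counts under-5 and 25-plus only
  mix <- data.frame(territory = "C", year = 2000,
                    age = c(2L, 10L, 30L), population = c(5, 7, 9))
  expect_equal(relevantPopulation(mix, "C"), 14)
})
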