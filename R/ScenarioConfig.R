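#' Define a synthetic study scenario
#'
#' Builds a [ScenarioConfig-class] describing the synthetic world on which
#' the pipeline runs: territories tiled over a regular lat/lon grid and
#' grouped into regions, each territory carrying a piecewise-linear PM2.5
#' exposure trajectory that changes slope at `breakpointYear`, a clustered
#' population raster, and demographic tables with population growth, aging
#' and declining baseline mortality.
#'
#' The defaults are the package's reference scenario: 24 territories in 6
#' regions over 22 years (1998-2019) with the trend reversal at 2011.
#' Base exposures span 15-60 \eqn{\mu g/m^3} and are positively associated
#' with territory population (populous territories are the polluted ones),
#' pre-breakpoint trends are uniformly positive (+0.3 to +1.5
#' \eqn{\mu g/m^3}/yr) while post-breakpoint trends turn negative for the
#' polluted, populous territories (down to -1.5 \eqn{\mu g/m^3}/yr), so
#' the global population-weighted series rises and then falls.  The
#' demographic rates (population growth 0.6%/yr, mean-age drift 0.15
#' yr/yr, baseline-mortality decline 1.2%/yr) are chosen so that, after
#' the breakpoint, extra deaths from population growth and aging
#' approximately offset the reductions from falling exposure and falling
#' mortality rates, producing a plateau in attributable mortality.
#'
#' @param nTerritories,nRegions number of territories and of regions.
#' @param years consecutive calendar years (span >= 3).
#' @param gridShape integer `c(rows, cols)` of the raster grid.
#' @param cellResolution cell size in degrees.
#' @param breakpointYear year at which exposure trends reverse (strictly
#'   inside `years`).
#' @param baseExposure,preTrend,postTrend per-territory exposure level in
#'   the first year and trends before/after the breakpoint
#'   (\eqn{\mu g/m^3}, \eqn{\mu g/m^3}/yr); scalars are recycled.
#' @param basePopulation per-territory population in the first year.
#' @param popGrowthRate,agingRate,mortalityDeclineRate per-territory
#'   annual demographic rates (fraction/yr, years/yr, fraction/yr).
#' @param baseMeanAge per-territory population mean age in the first year.
#' @param noiseSd standard deviation of i.i.d. Gaussian cell-level
#'   exposure noise (\eqn{\mu g/m^3}).
#' @param seed integer seed governing all scenario randomness.
#' @return a validated [ScenarioConfig-class].
#' @examples
#' cfg <- scenarioConfig(nTerritories = 4, nRegions = 2,
#'                       gridShape = c(12, 12), noiseSd = 0)
#' cfg
#' @export
scenarioConfig <- function(nTerritories = 24L,
                           nRegions = 6L,
                           years = 1998:2019,
                           gridShape = c(60L, 120L),
                           cellResolution = 0.1,
                           breakpointYear = 2011L,
                           baseExposure = seq(15, 60,
                                              length.out = nTerritories),
                           preTrend = seq(0.3, 1.5,
                                          length.out = nTerritories),
                           postTrend = seq(0.2, -1.5,
                                           length.out = nTerritories),
                           basePopulation = exp(seq(log(5e5), log(8e7),
                                                    length.out = nTerritories)),
                           popGrowthRate = 0.006,
                           agingRate = 0.15,
                           mortalityDeclineRate = 0.012,
                           baseMeanAge = 30,
                           noiseSd = 1,
                           seed = 42L) {
  nT <- as.integer(nTerritories)
  new("ScenarioConfig",
      nTerritories = nT, nRegions = as.integer(nRegions),
      years = as.integer(years),
      gridShape = as.integer(gridShape),
      cellResolution = as.numeric(cellResolution),
      breakpointYear = as.integer(breakpointYear),
      baseExposure = recycleTerr(baseExposure, nT, "baseExposure"),
      preTrend = recycleTerr(preTrend, nT, "preTrend"),
      postTrend = recycleTerr(postTrend, nT, "postTrend"),
      basePopulation = recycleTerr(basePopulation, nT, "basePopulation"),
      popGrowthRate = recycleTerr(popGrowthRate, nT, "popGrowthRate"),
      agingRate = recycleTerr(agingRate, nT, "agingRate"),
      mortalityDeclineRate = recycleTerr(mortalityDeclineRate, nT,
                                         "mortalityDeclineRate"),
      baseMeanAge = recycleTerr(baseMeanAge, nT, "baseMeanAge"),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig: %d territories / %d regions, %d-%d (breakpoint %d)\n",
              object@nTerritories, object@nRegions,
              min(object@years), max(object@years), object@breakpointYear))
  cat(sprintf("  grid %d x %d at %g deg, noise sd %g, seed %d\n",
              object@gridShape[1], object@gridShape[2],
              object@cellResolution, object@noiseSd, object@seed))
  cat(sprintf("  exposure %.1f-%.1f ug/m3; trends pre [%.2f, %.2f], post [%.2f, %.2f] ug/m3/yr\n",
              min(object@baseExposure), max(object@baseExposure),
              min(object@preTrend), max(object@preTrend),
              min(object@postTrend), max(object@postTrend)))
})

.configSlots <- c("nTerritories", "nRegions", "years", "gridShape",
                  "cellResolution", "breakpointYear", "baseExposure",
                  "preTrend", "postTrend", "basePopulation", "popGrowthRate",
                  "agingRate", "mortalityDeclineRate", "baseMeanAge",
                  "noiseSd", "seed")

#' Read or write a ScenarioConfig as YAML
#'
#' @param config a [ScenarioConfig-class].
#' @param path file path of the YAML document.
#' @return `readScenarioConfig` returns a [ScenarioConfig-class];
#'   `writeScenarioConfig` returns `path` invisibly.
#' @export
writeScenarioConfig <- function(config, path) {
  lst <- lapply(.configSlots, function(s) slot(config, s))
  names(lst) <- .configSlots
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeScenarioConfig
#' @export
readScenarioConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  unknown <- setdiff(names(lst), .configSlots)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(scenarioConfig, lst)
}

#' Tile the grid into territories and regions
#'
#' Deterministically partitions the scenario grid into contiguous
#' rectangular territory blocks (no RNG involved), and groups consecutive
#' territories into regions.  Territories are labelled `T01, T02, ...`
#' and regions `R1, R2, ...`.
#'
#' @param config a [ScenarioConfig-class].
#' @return a [TerritoryIndex-class] covering every cell of the grid.
#' @export
territoryLayout <- function(config) {
  validObject(config)
  nr <- config@gridShape[1]; nc <- config@gridShape[2]
  nT <- config@nTerritories
  # near-square block tiling with at least nT blocks
  ncb <- max(1L, min(nc, as.integer(ceiling(sqrt(nT * nc / nr)))))
  nrb <- as.integer(ceiling(nT / ncb))
  while (nrb > nr) { ncb <- ncb + 1L; nrb <- as.integer(ceiling(nT / ncb)) }
  # exact partitions: every block is non-empty, so every territory gets cells
  rowBlock <- 1L + as.integer(floor((seq_len(nr) - 1L) * nrb / nr))
  colBlock <- 1L + as.integer(floor((seq_len(nc) - 1L) * ncb / nc))
  block <- outer(rowBlock, colBlock, function(r, c) (r - 1L) * ncb + c)
  codes <- matrix(((block - 1L) %% nT) + 1L, nr, nc)
  territories <- sprintf("T%02d", seq_len(nT))
  perRegion <- ceiling(nT / config@nRegions)
  regions <- sprintf("R%d", 1L + (seq_len(nT) - 1L) %/% perRegion)
  territoryIndex(codes, territories, regions)
}

# per-territory deterministic mean exposure trajectory:
# base + preTrend*(y - y0) up to the breakpoint, then continuing from the
# breakpoint value with slope postTrend
territoryMeanExposure <- function(config, year) {
  y0 <- min(config@years); bp <- config@breakpointYear
  pre <- pmin(year, bp) - y0
  post <- max(0, year - bp)
  config@baseExposure + config@preTrend * pre + config@postTrend * post
}

# per-territory total population in a year (compound growth)
territoryPopulation <- function(config, year) {
  config@basePopulation *
    (1 + config@popGrowthRate)^(year - min(config@years))
}
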