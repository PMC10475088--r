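#' Generate annual PM2.5 exposure rasters for a scenario
#'
#' One raster per scenario year.  Each territory's spatial-mean
#' concentration follows its configured piecewise-linear trajectory
#' exactly in the noiseless case: a fixed, smooth spatial pattern with
#' zero mean inside every territory is superimposed on the territory mean,
#' then i.i.d. Gaussian noise with `noiseSd` is added per cell and values
#' are clipped at zero.  Fully deterministic given the config seed: the
#' noise stream for a year depends only on `(seed, year)`, so repeated
#' calls are bit-identical.
#'
#' @param config a [ScenarioConfig-class].
#' @param index a [TerritoryIndex-class]; defaults to
#'   [territoryLayout()] of the config.
#' @return named list (by year) of [RasterGrid-class] concentration
#'   rasters (\eqn{\mu g/m^3}).
#' @examples
#' cfg <- scenarioConfig(nTerritories = 4, nRegions = 2,
#'                       gridShape = c(10, 10), years = 1998:2002,
#'                       breakpointYear = 2000, noiseSd = 0)
#' pm <- generateExposureRasters(cfg)
#' mean(gridValues(pm[["1998"]]))
#' @export
generateExposureRasters <- function(config, index = territoryLayout(config)) {
  validObject(config)
  if (config@cellResolution <= 0)
    stop("cell resolution must be positive", call. = FALSE)
  if (length(config@years) == 0L)
    stop("empty year range", call. = FALSE)
  codes <- index@codes
  pattern <- spatialPattern(config, index)
  out <- lapply(config@years, function(y) {
    mu <- territoryMeanExposure(config, y)
    v <- matrix(mu[codes], nrow(codes), ncol(codes)) + pattern
    if (config@noiseSd > 0) {
      set.seed(substreamSeed(config@seed, y))
      v <- v + matrix(rnorm(length(v), sd = config@noiseSd),
                      nrow(v), ncol(v))
    }
    rasterGrid(pmax(v, 0), config@cellResolution)
  })
  names(out) <- as.character(config@years)
  out
}

# fixed smooth spatial texture, demeaned within each territory so the
# territory spatial mean is exactly the configured trajectory
spatialPattern <- function(config, index) {
  nr <- config@gridShape[1]; nc <- config@gridShape[2]
  amp <- min(4, min(config@baseExposure) / 4)
  sp <- amp * outer(sin(2 * pi * 3 * seq_len(nr) / nr),
                    cos(2 * pi * 2 * seq_len(nc) / nc))
  codes <- index@codes
  mns <- tapply(sp, codes, mean)
  sp - matrix(mns[as.character(codes)], nr, nc)
}

#' Generate a clustered population raster for one scenario year
#'
#' Population within each territory is concentrated in a few isotropic
#' Gaussian foci (urban clusters) over a small uniform rural background,
#' normalized so the territory total equals the scenario's demographic
#' total for that year (`basePopulation` compounded at `popGrowthRate`).
#' Foci locations are drawn once from the config seed, so the spatial
#' pattern is identical across years and calls; only the totals grow.
#'
#' @param config a [ScenarioConfig-class].
#' @param year a year inside the scenario range.
#' @param index a [TerritoryIndex-class].
#' @return a [RasterGrid-class] of persons per cell.
#' @export
generatePopulationRaster <- function(config, year,
                                     index = territoryLayout(config)) {
  validObject(config)
  if (!(year %in% config@years))
    stop(sprintf("year %s outside the scenario range %d-%d", year,
                 min(config@years), max(config@years)), call. = FALSE)
  dens <- populationDensity(config, index)
  totals <- territoryPopulation(config, year)
  codes <- index@codes
  terrDens <- tapply(dens, codes, sum)
  scale <- stats::setNames(totals[as.integer(names(terrDens))] / terrDens,
                           names(terrDens))
  v <- dens * matrix(scale[as.character(codes)], nrow(dens), ncol(dens))
  v[is.na(codes)] <- 0
  rasterGrid(v, config@cellResolution)
}

#' @rdname generatePopulationRaster
#' @return `generatePopulationRasters` returns a named list (by year) of
#'   [RasterGrid-class] objects.
#' @export
generatePopulationRasters <- function(config,
                                      index = territoryLayout(config)) {
  out <- lapply(config@years, generatePopulationRaster,
                config = config, index = index)
  names(out) <- as.character(config@years)
  out
}

# unnormalized density surface: per territory, 3 Gaussian foci plus a
# flat background; seeded from the config seed only (year-independent)
populationDensity <- function(config, index) {
  codes <- index@codes
  nr <- nrow(codes); nc <- ncol(codes)
  set.seed(substreamSeed(config@seed, 777L))
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  dens <- matrix(0, nr, nc)
  sigma <- max(1.5, sqrt(nr * nc / config@nTerritories) / 4)
  for (k in seq_len(config@nTerritories)) {
    cells <- which(codes == k)
    if (!length(cells)) next
    foci <- sample(cells, min(3L, length(cells)), replace = FALSE)
    fr <- rows[foci]; fc <- cols[foci]
    local <- 0.02
    for (f in seq_along(foci)) {
      d2 <- (rows[cells] - fr[f])^2 + (cols[cells] - fc[f])^2
      local <- local + exp(-d2 / (2 * sigma^2))
    }
    dens[cells] <- local
  }
  dens
}

#' Rescale a population raster to match per-territory totals
#'
#' Scales the population raster cell values within each territory so the
#' territory totals match an external demographic table (the standard
#' harmonization between a gridded population product and national
#' population tables).
#'
#' @param pop a [RasterGrid-class] of persons per cell.
#' @param index a [TerritoryIndex-class].
#' @param totals named numeric vector of target totals, names are
#'   territory identifiers.
#' @return a [RasterGrid-class] with matched totals.
#' @export
rescalePopulationRaster <- function(pop, index, totals) {
  codes <- index@codes
  if (!identical(dim(codes), dim(pop@values)))
    stop("population raster and territory index shapes differ", call. = FALSE)
  v <- pop@values
  for (k in seq_along(index@territories)) {
    cells <- which(codes == k)
    tot <- sum(v[cells], na.rm = TRUE)
    target <- totals[[index@territories[k]]]
    if (is.null(target) || is.na(target)) next
    v[cells] <- if (tot > 0) v[cells] * target / tot else target / length(cells)
  }
  new("RasterGrid", values = v, lat = pop@lat, lon = pop@lon,
      resolution = pop@resolution)
}
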