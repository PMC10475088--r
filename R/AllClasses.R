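# shared domain constants (defined here so they exist before any other
# file is collated)
.diseases <- c("IHD", "Stroke", "COPD", "LC", "DM", "LRI")
.ages <- 0:95

#' RasterGrid: a regular latitude/longitude grid of values
#'
#' Minimal container for a regular lat/lon raster holding either PM2.5
#' concentration (\eqn{\mu g/m^3}) or population counts (persons per cell).
#' Rows index latitude (increasing northwards), columns longitude
#' (increasing eastwards); coordinates are cell centers.  Missing cells are
#' `NA` and are excluded from every aggregation.
#'
#' @slot values numeric matrix of cell values, `NA` for nodata.
#' @slot lat numeric vector of cell-center latitudes, one per row,
#'   strictly increasing.
#' @slot lon numeric vector of cell-center longitudes, one per column,
#'   strictly increasing.
#' @slot resolution cell size in degrees (square cells).
#'
#' @seealso [rasterGrid()], [readAsciiGrid()], [writeAsciiGrid()]
#' @export
setClass("RasterGrid",
  representation(values = "matrix", lat = "numeric", lon = "numeric",
                 resolution = "numeric"))

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@values))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (nrow(object@values) != length(object@lat))
    msg <- c(msg, "length(lat) must equal nrow(values)")
  if (ncol(object@values) != length(object@lon))
    msg <- c(msg, "length(lon) must equal ncol(values)")
  if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
      object@resolution <= 0)
    msg <- c(msg, "'resolution' must be a single positive number")
  if (length(object@lat) > 1L && any(diff(object@lat) <= 0))
    msg <- c(msg, "'lat' must be strictly increasing")
  if (length(object@lon) > 1L && any(diff(object@lon) <= 0))
    msg <- c(msg, "'lon' must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' TerritoryIndex: cell-to-territory membership and regional grouping
#'
#' Maps every grid cell to a territory and every territory to exactly one
#' region, mirroring a world of territories grouped into
#' larger reporting regions.  Cells with `NA` code belong to no territory
#' (e.g. ocean) and are excluded from territorial aggregations.
#'
#' @slot codes integer matrix, same shape as the companion rasters; entry
#'   is the territory index (into `territories`) or `NA`.
#' @slot territories character vector of territory identifiers.
#' @slot regions character vector, same length as `territories`, giving
#'   the region of each territory.
#'
#' @seealso [territoryLayout()], [territoryNames()], [territoryRegions()]
#' @export
setClass("TerritoryIndex",
  representation(codes = "matrix", territories = "character",
                 regions = "character"))

setValidity("TerritoryIndex", function(object) {
  msg <- character()
  nT <- length(object@territories)
  if (length(object@regions) != nT)
    msg <- c(msg, "'regions' must have one entry per territory")
  if (anyDuplicated(object@territories))
    msg <- c(msg, "territory identifiers must be unique")
  cd <- object@codes[!is.na(object@codes)]
  if (length(cd) && (any(cd < 1L) || any(cd > nT)))
    msg <- c(msg, "territory codes must index into 'territories'")
  if (length(msg)) msg else TRUE
})

#' ScenarioConfig: parameters of the synthetic study scenario
#'
#' Describes a synthetic world of territories grouped into regions on a
#' regular grid, with territory-specific piecewise-linear PM2.5 exposure
#' trends that reverse at a breakpoint year, clustered population rasters,
#' and demographic tables with configurable population growth, aging and
#' declining baseline mortality rates.  All per-territory parameters are
#' stored as length-`nTerritories` vectors (scalars are recycled by the
#' [scenarioConfig()] constructor).
#'
#' @slot nTerritories,nRegions integer counts.
#' @slot years integer vector of consecutive calendar years (span >= 3).
#' @slot gridShape integer `c(rows, cols)` of the raster grid.
#' @slot cellResolution cell size in degrees.
#' @slot breakpointYear year at which exposure trends reverse; strictly
#'   inside `years`.
#' @slot baseExposure territory mean exposure in the first year
#'   (\eqn{\mu g/m^3}), positive.
#' @slot preTrend,postTrend exposure trends before/after the breakpoint
#'   (\eqn{\mu g/m^3}/year).
#' @slot basePopulation territory population in the first year (persons).
#' @slot popGrowthRate annual population growth rate (fraction/year).
#' @slot agingRate drift of population mean age (years/year).
#' @slot mortalityDeclineRate annual decline of baseline mortality rates
#'   (fraction/year).
#' @slot baseMeanAge population mean age in the first year (years).
#' @slot noiseSd standard deviation of i.i.d. cell-level exposure noise
#'   (\eqn{\mu g/m^3}).
#' @slot seed integer RNG seed governing all randomness of the scenario.
#'
#' @seealso [scenarioConfig()]
#' @export
setClass("ScenarioConfig",
  representation(nTerritories = "integer", nRegions = "integer",
                 years = "integer", gridShape = "integer",
                 cellResolution = "numeric", breakpointYear = "integer",
                 baseExposure = "numeric", preTrend = "numeric",
                 postTrend = "numeric", basePopulation = "numeric",
                 popGrowthRate = "numeric", agingRate = "numeric",
                 mortalityDeclineRate = "numeric", baseMeanAge = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  nT <- object@nTerritories
  if (length(object@years) < 3L)
    msg <- c(msg, "year range must span at least 3 years")
  if (length(object@years) && any(diff(object@years) != 1L))
    msg <- c(msg, "years must be consecutive")
  if (!(object@breakpointYear > min(object@years) &&
        object@breakpointYear < max(object@years)))
    msg <- c(msg, "breakpointYear must lie strictly inside the year range")
  if (any(object@baseExposure <= 0))
    msg <- c(msg, "baseExposure must be positive")
  if (length(object@gridShape) != 2L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be two positive integers")
  else if (prod(object@gridShape) < nT)
    msg <- c(msg, "grid must have at least one cell per territory")
  if (object@cellResolution <= 0)
    msg <- c(msg, "cellResolution must be positive")
  if (object@nRegions < 1L || object@nRegions > nT)
    msg <- c(msg, "nRegions must be between 1 and nTerritories")
  for (sl in c("baseExposure", "preTrend", "postTrend", "basePopulation",
               "popGrowthRate", "agingRate", "mortalityDeclineRate",
               "baseMeanAge")) {
    if (length(slot(object, sl)) != nT)
      msg <- c(msg, sprintf("'%s' must have one value per territory", sl))
  }
  if (any(object@basePopulation < 0))
    msg <- c(msg, "basePopulation must be non-negative")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CRFSpec: one GEMM-form concentration-response curve
#'
#' A parametric relative-risk curve for one (disease, age band), in the
#' Global Exposure Mortality Model (GEMM) functional form
#' \deqn{RR(E) = \exp\left(\theta \frac{\log(1 + z/\alpha)}
#'   {1 + \exp(-(z-\mu)/\nu)}\right), \quad z = \max(0, E - z_{cf}),}
#' normalized so that \eqn{RR = 1} at the counterfactual concentration
#' \eqn{z_{cf}} (theoretical minimum-risk exposure level).  The 95%
#' confidence band is carried as lower/central/upper values of
#' \eqn{\theta}; because the curve is monotone in \eqn{\theta} the three
#' variants are ordered pointwise at every concentration.
#'
#' @slot disease one of IHD, Stroke, COPD, LC, DM, LRI.
#' @slot ageLo,ageHi inclusive age band covered by the curve (`Inf` for
#'   open-ended upper bands).
#' @slot theta named numeric `c(lower=, central=, upper=)` log-hazard
#'   scale parameters, `lower <= central <= upper`.
#' @slot alpha,mu,nu positive shape parameters (\eqn{\mu} may be any
#'   finite value).
#' @slot zCf counterfactual concentration (\eqn{\mu g/m^3}).
#'
#' @seealso [crfSpec()], [gemmRR()], [defaultCRFParameters()]
#' @export
setClass("CRFSpec",
  representation(disease = "character", ageLo = "numeric", ageHi = "numeric",
                 theta = "numeric", alpha = "numeric", mu = "numeric",
                 nu = "numeric", zCf = "numeric"))

setValidity("CRFSpec", function(object) {
  msg <- character()
  if (!object@disease %in% .diseases)
    msg <- c(msg, sprintf("unknown disease '%s'", object@disease))
  th <- object@theta
  if (length(th) != 3L ||
      !identical(names(th), c("lower", "central", "upper")))
    msg <- c(msg, "'theta' must be named c(lower=, central=, upper=)")
  else if (!(th["lower"] <= th["central"] && th["central"] <= th["upper"]))
    msg <- c(msg, "theta variants must satisfy lower <= central <= upper")
  else if (th["lower"] < 0)
    msg <- c(msg, "theta must be non-negative (hazard cannot decrease)")
  if (object@alpha <= 0) msg <- c(msg, "'alpha' must be positive")
  if (object@nu <= 0) msg <- c(msg, "'nu' must be positive")
  if (object@zCf < 0) msg <- c(msg, "'zCf' must be non-negative")
  if (object@ageLo > object@ageHi)
    msg <- c(msg, "ageLo must not exceed ageHi")
  if (length(msg)) msg else TRUE
})

#' CRFSet: a collection of concentration-response curves
#'
#' A plain list of [CRFSpec-class] objects covering every eligible
#' (disease, age) combination, with a class tag so lookup and show methods
#' can dispatch on it.
#'
#' @seealso [defaultCRFParameters()], [crfFor()]
#' @export
setClass("CRFSet", contains = "list")

setValidity("CRFSet", function(object) {
  if (!all(vapply(object@.Data, is, logical(1), "CRFSpec")))
    return("all elements must be CRFSpec objects")
  TRUE
})
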