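#' Population-weighted mean exposure over a scope
#'
#' \deqn{E = \sum_l PM_l P_l \Big/ \sum_l P_l} over the scope's cells.
#' Cells with missing concentration are excluded from both numerator and
#' denominator (weight renormalization); a message is emitted when this
#' drops populated cells.
#'
#' @param pm [RasterGrid-class] of concentrations (\eqn{\mu g/m^3}).
#' @param pop [RasterGrid-class] of population counts, same grid.
#' @param index [TerritoryIndex-class] defining scopes; may be `NULL`
#'   when `scope = "global"`, in which case all cells count.
#' @param scope `"global"`, a region name, or territory identifier(s).
#' @return list with `E` (population-weighted mean) and `population`
#'   (scope population used as weight mass).
#' @examples
#' pm <- rasterGrid(matrix(c(10, 30), 1, 2), 0.1)
#' pop <- rasterGrid(matrix(c(1, 3), 1, 2), 0.1)
#' pwExposure(pm, pop)$E  # 25
#' @export
pwExposure <- function(pm, pop, index = NULL, scope = "global") {
  if (!sameGrid(pm, pop))
    stop("concentration and population rasters are not on the same grid",
         call. = FALSE)
  if (is.null(index)) {
    if (!identical(scope, "global"))
      stop("a TerritoryIndex is required for sub-global scopes",
           call. = FALSE)
    mask <- matrix(TRUE, nrow(pm@values), ncol(pm@values))
  } else {
    if (!identical(dim(index@codes), dim(pm@values)))
      stop("territory index and raster shapes differ", call. = FALSE)
    mask <- scopeMask(index, scope)
  }
  pmv <- pm@values[mask]
  popv <- pop@values[mask]
  popv[is.na(popv)] <- 0
  drop <- is.na(pmv)
  if (any(drop & popv > 0))
    message(sprintf("pwExposure: excluding %d populated cells with missing concentration",
                    sum(drop & popv > 0)))
  pmv <- pmv[!drop]; popv <- popv[!drop]
  totPop <- sum(popv)
  if (!(totPop > 0))
    stop(sprintf("scope '%s' has zero population: population-weighted exposure undefined",
                 paste(scope, collapse = ",")), call. = FALSE)
  list(E = sum(pmv * popv) / totPop, population = totPop)
}

#' Annual population-weighted exposure series for all scopes
#'
#' Computes, for every scenario year, the population-weighted exposure
#' `E` and population `P` of every territory, every region and the
#' globe, plus for sub-global scopes the normalized exposure
#' \eqn{NE_k = E_k P_k / P_{global}} and its share \eqn{NE_k/E_{global}}.
#' By construction the normalized values of the regions (and of the
#' territories) sum to the global exposure each year.
#'
#' @param pmRasters named list (by year) of concentration
#'   [RasterGrid-class] objects.
#' @param popRasters named list (by year) of population rasters on the
#'   same grid.
#' @param index a [TerritoryIndex-class].
#' @return data.frame with columns scope, scope_type
#'   (territory/region/global), region, year, E, population, NE, share.
#' @export
exposureSeries <- function(pmRasters, popRasters, index) {
  years <- names(pmRasters)
  if (!identical(years, names(popRasters)))
    stop("exposure and population raster lists cover different years",
         call. = FALSE)
  regions <- territoryRegions(index)
  rows <- lapply(years, function(yr) {
    pm <- pmRasters[[yr]]; pop <- popRasters[[yr]]
    terr <- lapply(index@territories, function(tk)
      pwExposure(pm, pop, index, tk))
    Ek <- vapply(terr, `[[`, numeric(1), "E")
    Pk <- vapply(terr, `[[`, numeric(1), "population")
    Pg <- sum(Pk)
    Eg <- sum(Ek * Pk) / Pg
    tdf <- data.frame(scope = index@territories, scope_type = "territory",
                      region = unname(regions[index@territories]),
                      year = as.integer(yr), E = Ek, population = Pk,
                      NE = normalizedPw(Ek, Pk, Pg))
    regAgg <- lapply(regionNames(index), function(r) {
      kk <- index@regions == r
      Pr <- sum(Pk[kk])
      data.frame(scope = r, scope_type = "region", region = r,
                 year = as.integer(yr), E = sum(Ek[kk] * Pk[kk]) / Pr,
                 population = Pr,
                 NE = normalizedPw(sum(Ek[kk] * Pk[kk]) / Pr, Pr, Pg))
    })
    gdf <- data.frame(scope = "global", scope_type = "global",
                      region = NA_character_, year = as.integer(yr),
                      E = Eg, population = Pg, NE = NA_real_)
    out <- rbind(tdf, do.call(rbind, regAgg), gdf)
    out$share <- contributionShare(out$NE, Eg)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalized population-weighted exposure
#'
#' \deqn{NE_k = E_k P_k / P_{global}}: a scope's exposure scaled by its
#' share of global population, so that scopes partitioning the globe sum
#' to the global population-weighted exposure.
#'
#' @param E scope population-weighted exposure(s) (\eqn{\mu g/m^3}).
#' @param population scope population(s).
#' @param globalPopulation total population of the enclosing (global)
#'   scope; must be positive.
#' @return normalized exposure(s), \eqn{\mu g/m^3}.
#' @examples
#' normalizedPw(36.9, 0.214, 1)  # 7.9 at one decimal
#' @export
normalizedPw <- function(E, population, globalPopulation) {
  if (!(globalPopulation > 0))
    stop("global population must be positive", call. = FALSE)
  E * population / globalPopulation
}

#' Share of global exposure carried by a normalized contribution
#'
#' @param NE normalized exposure(s) (\eqn{\mu g/m^3}).
#' @param Eglobal global population-weighted exposure; must be positive.
#' @return fraction(s) `NE / Eglobal`; over a partition of the globe
#'   these sum to 1.
#' @export
contributionShare <- function(NE, Eglobal) {
  if (!(Eglobal > 0))
    stop("global exposure must be positive", call. = FALSE)
  NE / Eglobal
}

#' Counterfactual exposure projections
#'
#' Projects a scope's exposure series beyond a pivot year under one of
#' two counterfactuals: `extend_pre_trend` continues the
#' ordinary-least-squares slope fitted to the years up to and including
#' the pivot ("business as usual"), `hold_at_pivot` freezes exposure at
#' its pivot-year value.  Projected concentrations are floored at zero.
#'
#' @param series data.frame with columns `year` and `E` for one scope.
#' @param mode `"extend_pre_trend"` or `"hold_at_pivot"`.
#' @param pivotYear pivot year, present in `series`.
#' @param horizonYear last projected year (> pivot).
#' @return data.frame with columns year, E (counterfactual values from
#'   pivot to horizon inclusive).
#' @export
projectCounterfactual <- function(series,
                                  mode = c("extend_pre_trend",
                                           "hold_at_pivot"),
                                  pivotYear, horizonYear) {
  mode <- match.arg(mode)
  if (!pivotYear %in% series$year)
    stop("pivot year not present in the series", call. = FALSE)
  Epivot <- series$E[series$year == pivotYear]
  years <- pivotYear:horizonYear
  if (mode == "hold_at_pivot") {
    Ecf <- rep(Epivot, length(years))
  } else {
    pre <- series[series$year <= pivotYear, ]
    if (nrow(pre) < 3L)
      stop("need at least 3 pre-pivot years to extend the trend",
           call. = FALSE)
    slope <- olsTrend(pre$year, pre$E)$slope
    Ecf <- Epivot + slope * (years - pivotYear)
  }
  data.frame(year = years, E = pmax(Ecf, 0))
}
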