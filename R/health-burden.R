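# map every (age, disease) cell to the index of its curve in the set;
# NA where the cell is outside the disease's eligible ages
crfIndexTable <- function(crfs) {
  idx <- matrix(NA_integer_, length(.ages), length(.diseases),
                dimnames = list(.ages, .diseases))
  for (ci in seq_along(crfs@.Data)) {
    s <- crfs@.Data[[ci]]
    ages <- .ages[.ages >= s@ageLo & .ages <= s@ageHi]
    idx[as.character(ages), s@disease] <- ci
  }
  idx
}

# evaluate PAF for parallel vectors of (disease, age, E); grouped by curve
pafVector <- function(crfs, disease, age, E, variant = "central") {
  idx <- crfIndexTable(crfs)
  ci <- idx[cbind(match(age, .ages), match(disease, .diseases))]
  if (anyNA(ci)) {
    bad <- which(is.na(ci))[1]
    stop(sprintf("no concentration-response curve for %s at age %s",
                 disease[bad], age[bad]), call. = FALSE)
  }
  out <- numeric(length(E))
  for (u in unique(ci)) {
    sel <- ci == u
    out[sel] <- paf(crfs@.Data[[u]], E[sel], variant)
  }
  out
}

#' PM2.5-attributable deaths per territory and year
#'
#' \deqn{D_{PM} = \sum_i \sum_j D_{i,j} \, PAF_{i,j}(E)} over eligible
#' ages i and diseases j, with each territory evaluated at its own
#' population-weighted exposure.  The 95% confidence interval is obtained
#' by re-evaluating with the lower and upper parameter variants of every
#' curve; the overall attributable fraction `paf_a` is the
#' deaths-weighted mean PAF (central variant), and `pop_relevant` (when
#' demography is supplied) is the population at ages under 5 or 25+.
#'
#' @param deaths baseline-deaths data.frame (territory, year, age,
#'   disease, deaths); validated with [validateDeathsTable()].
#' @param exposure data.frame with territory exposure per year: columns
#'   `scope` (or `territory`), `year`, `E` — e.g. the territory rows of
#'   [exposureSeries()].
#' @param crfs a [CRFSet-class].
#' @param demography optional population data.frame (territory, year,
#'   age, population) used for `pop_relevant`.
#' @return data.frame with one row per territory-year: scope, year,
#'   central, lower, upper, deaths_total, paf_a, pop_relevant.
#' @export
attributableDeaths <- function(deaths, exposure, crfs, demography = NULL) {
  validateDeathsTable(deaths)
  if ("territory" %in% names(exposure) && !"scope" %in% names(exposure))
    exposure$scope <- exposure$territory
  key <- paste(deaths$territory, deaths$year)
  ekey <- paste(exposure$scope, exposure$year)
  E <- exposure$E[match(key, ekey)]
  if (anyNA(E))
    stop("exposure missing for some territory-years in the deaths table",
         call. = FALSE)
  pafs <- lapply(c(central = "central", lower = "lower", upper = "upper"),
                 function(v) pafVector(crfs, deaths$disease, deaths$age,
                                       E, v))
  agg <- function(x) {
    a <- aggregate(x, list(scope = deaths$territory, year = deaths$year),
                   sum)
    a[order(a$scope, a$year), ]
  }
  out <- agg(deaths$deaths * pafs$central)
  names(out)[3] <- "central"
  out$lower <- agg(deaths$deaths * pafs$lower)$x
  out$upper <- agg(deaths$deaths * pafs$upper)$x
  out$deaths_total <- agg(deaths$deaths)$x
  out$paf_a <- out$central / out$deaths_total
  out$pop_relevant <- NA_real_
  if (!is.null(demography)) {
    rel <- demography[demography$age < 5 | demography$age >= 25, ]
    ra <- aggregate(rel$population,
                    list(scope = rel$territory, year = rel$year), sum)
    out$pop_relevant <- ra$x[match(paste(out$scope, out$year),
                                   paste(ra$scope, ra$year))]
  }
  rownames(out) <- NULL
  out
}

#' Aggregate a territory-level burden table to regions or the globe
#'
#' Sums attributable deaths (all variants), baseline deaths and relevant
#' population over member territories; `paf_a` is recomputed as the
#' aggregate deaths-weighted attributable fraction.
#'
#' @param burden an [attributableDeaths()] data.frame.
#' @param index a [TerritoryIndex-class].
#' @param level `"region"` or `"global"`.
#' @return data.frame of the same shape with aggregated scopes.
#' @export
aggregateBurden <- function(burden, index, level = c("region", "global")) {
  level <- match.arg(level)
  regions <- territoryRegions(index)
  grp <- if (level == "region") unname(regions[burden$scope])
         else rep("global", nrow(burden))
  cols <- intersect(c("central", "lower", "upper", "deaths_total",
                      "pop_relevant"), names(burden))
  a <- aggregate(burden[cols], list(scope = grp, year = burden$year), sum)
  a$paf_a <- a$central / a$deaths_total
  a[order(a$scope, a$year), ]
}

#' Overall population attributable fraction of a deaths table
#'
#' \deqn{PAF_a = \sum_{i,j} D_{i,j} PAF_{i,j} \big/ \sum_{i,j} D_{i,j}}:
#' the deaths-weighted mean attributable fraction over all eligible ages
#' and diseases, identical to attributable deaths divided by total
#' eligible baseline deaths.
#'
#' @inheritParams attributableDeaths
#' @return data.frame scope, year, paf_a.
#' @export
overallPaf <- function(deaths, exposure, crfs) {
  b <- attributableDeaths(deaths, exposure, crfs)
  if (any(b$deaths_total <= 0))
    stop("zero eligible deaths in some territory-year", call. = FALSE)
  b[, c("scope", "year", "paf_a")]
}

#' Aggregate baseline mortality rate of a scope
#'
#' \deqn{MR = \sum_{i,j,k} D_{i,j,k} \big/ \sum_{i,k} P_{i,k}}: total
#' deaths (over the table's ages and diseases) divided by total
#' population of the same scope.
#'
#' @param deaths baseline-deaths data.frame.
#' @param demography population data.frame (territory, year, age,
#'   population).
#' @param scope territory identifier(s) or `"global"` for all.
#' @param year optional year filter; default uses all rows.
#' @return deaths per person per year.
#' @export
mortalityRate <- function(deaths, demography, scope = "global",
                          year = NULL) {
  d <- filterScope(deaths, scope, year)
  p <- filterScope(demography, scope, year)
  tot <- sum(p$population)
  if (!(tot > 0)) stop("zero scope population", call. = FALSE)
  sum(d$deaths) / tot
}

#' Population mean age of a scope
#'
#' \deqn{Age_m = \sum_{i,k} Age_{i,k} P_{i,k} \big/ \sum_{i,k} P_{i,k}}
#' with the boundary convention that the `<1` bin carries age 0 and the
#' `95+` bin age 95.
#'
#' @inheritParams mortalityRate
#' @return mean age in years.
#' @export
meanAge <- function(demography, scope = "global", year = NULL) {
  p <- filterScope(demography, scope, year)
  tot <- sum(p$population)
  if (!(tot > 0)) stop("zero scope population", call. = FALSE)
  sum(p$age * p$population) / tot
}

#' Population at ages relevant to PM2.5-attributable mortality
#'
#' The ages that contribute to at least one of the six diseases: under 5
#' (childhood LRI) or 25 and older (all diseases).
#'
#' @inheritParams mortalityRate
#' @return persons.
#' @export
relevantPopulation <- function(demography, scope = "global", year = NULL) {
  p <- filterScope(demography, scope, year)
  sum(p$population[p$age < 5 | p$age >= 25])
}

filterScope <- function(df, scope, year = NULL) {
  if (!identical(scope, "global"))
    df <- df[df$territory %in% scope, ]
  if (!is.null(year))
    df <- df[df$year %in% year, ]
  df
}
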