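# Internal disease parameters for the synthetic baseline-mortality curves:
# adult rates follow a Gompertz-like exp(k * (age - 25)) shape anchored at
# age 25; LRI additionally has a flat childhood (<5) rate.
.mortalityShape <- data.frame(
  disease = .diseases,
  rate25 = c(1.5e-4, 1.0e-4, 6e-5, 8e-5, 4e-5, 2e-5),
  gompertz = c(0.090, 0.095, 0.100, 0.070, 0.080, 0.100),
  childRate = c(0, 0, 0, 0, 0, 8e-4),
  stringsAsFactors = FALSE)

# exponential age pyramid weight scale solved so the population mean age
# hits a target; mean age of w ~ exp(-a/s), a = 0..95, is increasing in s
pyramidScale <- function(targetMean) {
  f <- function(s) {
    w <- exp(-.ages / s)
    sum(.ages * w) / sum(w) - targetMean
  }
  uniroot(f, c(0.5, 5000), tol = 1e-10)$root
}

#' Generate synthetic demography and baseline-deaths tables
#'
#' Produces the two tabular inputs of the health-burden stage for every
#' territory and scenario year:
#' \describe{
#'   \item{population}{single-year ages 0-95 (the `<1` bin mapped to age 0
#'     and the `95+` bin to 95), with an exponential age pyramid whose
#'     mean age drifts upwards at the configured `agingRate` and totals
#'     compounding at `popGrowthRate`.}
#'   \item{deaths}{per-age, per-disease baseline deaths for the six
#'     diseases linked to PM2.5 (IHD, Stroke, COPD, LC, DM, LRI), from
#'     Gompertz-like age-specific mortality-rate curves declining at
#'     `mortalityDeclineRate`.  The disease-age eligibility rule is built
#'     in: LRI deaths exist for ages under 5 and 25+, the other five
#'     diseases for ages 25+ only.}
#' }
#' The construction is deterministic (no RNG): mean-age targets are hit
#' by solving the pyramid scale per territory-year.
#'
#' @param config a [ScenarioConfig-class].
#' @param index a [TerritoryIndex-class] (used only for region labels).
#' @return list with data.frames `population` (territory, region, year,
#'   age, population) and `deaths` (territory, region, year, age, disease,
#'   deaths).
#' @examples
#' cfg <- scenarioConfig(nTerritories = 2, nRegions = 1,
#'                       gridShape = c(4, 4), years = 1998:2001,
#'                       breakpointYear = 2000)
#' dem <- generateDemography(cfg)
#' head(dem$population)
#' @export
generateDemography <- function(config, index = territoryLayout(config)) {
  validObject(config)
  regions <- territoryRegions(index)
  years <- config@years; y0 <- min(years)
  nT <- config@nTerritories
  nA <- length(.ages)
  sh <- .mortalityShape
  popList <- vector("list", nT * length(years))
  deathList <- vector("list", nT * length(years))
  ix <- 0L
  for (k in seq_len(nT)) {
    terr <- index@territories[k]
    for (y in years) {
      t <- y - y0
      total <- territoryPopulation(config, y)[k]
      target <- min(config@baseMeanAge[k] + config@agingRate[k] * t, 45)
      w <- exp(-.ages / pyramidScale(target))
      popAge <- total * w / sum(w)
      decline <- (1 - config@mortalityDeclineRate[k])^t
      ix <- ix + 1L
      popList[[ix]] <- data.frame(
        territory = terr, region = regions[[terr]], year = y,
        age = .ages, population = popAge)
      dl <- lapply(seq_len(nrow(sh)), function(j) {
        ages <- eligibleAges(sh$disease[j])
        mr <- ifelse(ages < 5, sh$childRate[j],
                     sh$rate25[j] * exp(sh$gompertz[j] * (ages - 25)))
        data.frame(territory = terr, region = regions[[terr]], year = y,
                   age = ages, disease = sh$disease[j],
                   deaths = popAge[match(ages, .ages)] * mr * decline)
      })
      deathList[[ix]] <- do.call(rbind, dl)
    }
  }
  pop <- do.call(rbind, popList)
  deaths <- do.call(rbind, deathList)
  rownames(pop) <- rownames(deaths) <- NULL
  list(population = pop, deaths = deaths)
}

#' Validate a baseline-deaths table
#'
#' Checks the structural invariants a deaths table must satisfy before it
#' enters the burden computation: required columns, known diseases,
#' non-negative counts, and the disease-age eligibility rule (LRI: ages
#' under 5 or 25+; all others: 25+ only).
#'
#' @param deaths data.frame with columns territory, year, age, disease,
#'   deaths.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validateDeathsTable <- function(deaths) {
  need <- c("territory", "year", "age", "disease", "deaths")
  miss <- setdiff(need, names(deaths))
  if (length(miss))
    stop("deaths table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(deaths$disease), .diseases)
  if (length(bad))
    stop("unknown diseases: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(deaths$deaths < 0))
    stop("negative death counts", call. = FALSE)
  ok <- isEligibleAge(deaths$disease, deaths$age)
  if (any(!ok & deaths$deaths > 0))
    stop("deaths present outside disease-age eligibility (LRI: <5 or >=25; others: >=25)",
         call. = FALSE)
  invisible(deaths)
}
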