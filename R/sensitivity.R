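#' Finite-difference sensitivity of the attributable fraction
#'
#' Central-difference slope of PAF with respect to exposure:
#' \deqn{\Delta PAF/\Delta E = [PAF(E+\Delta E) - PAF(E-\Delta E)] /
#'   (2\Delta E)} with \eqn{\Delta E} set to `relDelta * E` and the full
#' window \eqn{2\Delta E} clamped into `[clampLo, clampHi]`
#' (\eqn{\mu g/m^3}) before splitting it symmetrically.  If the lower
#' evaluation point would fall below zero (only possible at very low
#' exposure), a forward difference over `[E, E + 2dE]` is used instead
#' and a message is emitted.
#'
#' @param crf a [CRFSpec-class].
#' @param E exposure (\eqn{\mu g/m^3}), scalar.
#' @param relDelta relative half-step (default 0.05, i.e. +/-5%).
#' @param clampLo,clampHi bounds on the full difference window
#'   \eqn{2\Delta E} (defaults 1 and 5 \eqn{\mu g/m^3}); tests may shrink
#'   them to study convergence to the analytic derivative.
#' @param variant parameter variant, as in [gemmRR()].
#' @return list with `sens` (per \eqn{\mu g/m^3}), `deltaUsed` (the
#'   realized \eqn{2\Delta E}) and `forward` (logical).
#' @export
pafSensitivity <- function(crf, E, relDelta = 0.05, clampLo = 1,
                           clampHi = 5, variant = "central") {
  twoDelta <- clampValue(2 * relDelta * E, clampLo, clampHi)
  lo <- E - twoDelta / 2
  forward <- lo < 0
  if (forward) {
    message(sprintf("pafSensitivity: forward difference at E = %.3g", E))
    lo <- E
  }
  hi <- lo + twoDelta
  sens <- (paf(crf, hi, variant) - paf(crf, lo, variant)) / twoDelta
  list(sens = sens, deltaUsed = twoDelta, forward = forward)
}

# sensitivity for parallel vectors of (disease, age) cells at a common
# scalar exposure; vectorized by curve
pafSensVector <- function(crfs, disease, age, E, relDelta = 0.05,
                          clampLo = 1, clampHi = 5, variant = "central") {
  idx <- crfIndexTable(crfs)
  ci <- idx[cbind(match(age, .ages), match(disease, .diseases))]
  if (anyNA(ci))
    stop("missing concentration-response curve for some cells",
         call. = FALSE)
  twoDelta <- clampValue(2 * relDelta * E, clampLo, clampHi)
  lo <- E - twoDelta / 2
  if (lo < 0) lo <- E
  hi <- lo + twoDelta
  out <- numeric(length(ci))
  for (u in unique(ci)) {
    s <- crfs@.Data[[u]]
    out[ci == u] <- (paf(s, hi, variant) - paf(s, lo, variant)) / twoDelta
  }
  out
}

#' Marginal health benefit of exposure mitigation
#'
#' Sensitivity of attributable deaths to a marginal change in
#' population-weighted exposure, per territory-year:
#' \deqn{\Delta D_{PM}/\Delta E = \sum_i \sum_j D_{i,j} \,
#'   \Delta PAF_{i,j}/\Delta E,} using the clamped central difference of
#' [pafSensitivity()].  The per-capita version divides by the relevant
#' population (ages under 5 or 25+) and is reported as annual deaths per
#' million persons per \eqn{\mu g/m^3}.
#'
#' @inheritParams attributableDeaths
#' @param demography population data.frame used for the per-capita
#'   normalization.
#' @param relDelta,clampLo,clampHi finite-difference controls, see
#'   [pafSensitivity()].
#' @return data.frame per territory-year: scope, year, dDdE (deaths per
#'   \eqn{\mu g/m^3}), per_capita (deaths per million relevant persons
#'   per \eqn{\mu g/m^3}), delta_used (\eqn{\mu g/m^3}).
#' @export
marginalBenefit <- function(deaths, exposure, demography, crfs,
                            relDelta = 0.05, clampLo = 1, clampHi = 5) {
  validateDeathsTable(deaths)
  if ("territory" %in% names(exposure) && !"scope" %in% names(exposure))
    exposure$scope <- exposure$territory
  keys <- unique(deaths[, c("territory", "year")])
  ekey <- paste(exposure$scope, exposure$year)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    terr <- keys$territory[i]; yr <- keys$year[i]
    E <- exposure$E[match(paste(terr, yr), ekey)]
    if (is.na(E))
      stop(sprintf("no exposure for %s in %s", terr, yr), call. = FALSE)
    d <- deaths[deaths$territory == terr & deaths$year == yr, ]
    sens <- pafSensVector(crfs, d$disease, d$age, E, relDelta,
                          clampLo, clampHi)
    relPop <- relevantPopulation(demography, terr, yr)
    if (!(relPop > 0))
      stop(sprintf("zero relevant population for %s in %s", terr, yr),
           call. = FALSE)
    data.frame(scope = terr, year = yr, dDdE = sum(d$deaths * sens),
               per_capita = sum(d$deaths * sens) / relPop * 1e6,
               delta_used = clampValue(2 * relDelta * E, clampLo, clampHi),
               pop_relevant = relPop)
  })
  out <- do.call(rbind, rows)
  out[order(out$scope, out$year), ]
}

#' Aggregate a territory-level marginal-benefit table
#'
#' Sums `dDdE` and the relevant population over member territories (each
#' territory evaluated at its own exposure) and recomputes the
#' per-capita rate.
#'
#' @param benefit a [marginalBenefit()] data.frame.
#' @param index a [TerritoryIndex-class].
#' @param level `"region"` or `"global"`.
#' @return aggregated data.frame.
#' @export
aggregateBenefit <- function(benefit, index, level = c("region", "global")) {
  level <- match.arg(level)
  regions <- territoryRegions(index)
  grp <- if (level == "region") unname(regions[benefit$scope])
         else rep("global", nrow(benefit))
  a <- aggregate(benefit[c("dDdE", "pop_relevant")],
                 list(scope = grp, year = benefit$year), sum)
  a$per_capita <- a$dDdE / a$pop_relevant * 1e6
  a[order(a$scope, a$year), ]
}
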