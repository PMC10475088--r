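# The order-ensemble decomposition attributes year-over-year changes in
# attributable mortality to four multiplicative drivers per
# (territory, age, disease) cell:
#   D_PM(i,j,k) = P_k * AF_{i,k} * MR_{i,j,k} * PAF_{i,j}(E_k)
# with P total population, AF the age-structure fraction, MR the baseline
# mortality rate and PAF the attributable fraction at the territory's
# population-weighted exposure.  Switching the four factors from year y
# to year y+1 one at a time defines 24 (= 4!) orderings; each factor's
# contribution is its marginal change averaged over all orderings (its
# Shapley value), which conserves the total change exactly.

.factors <- c("P", "AF", "MR", "PAF")

#' Enumerate the factor-switching orderings
#'
#' All orderings in which the four drivers (P, AF, MR, PAF) can be
#' switched from one year to the next; there are exactly
#' \eqn{4! = 24}.
#'
#' @return a 24 x 4 character matrix, one ordering per row.
#' @export
factorOrderings <- function() {
  perm <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perm(v[-i]), deparse.level = 0)))
  }
  perm(.factors)
}

#' Build yearly factor states from demography, deaths and exposure
#'
#' Converts the tabular inputs into one state per year holding, for every
#' territory: total population `P`, the age-fraction matrix `AF` (ages
#' 0-95, columns sum to 1), the mortality-rate array `MR` (age x disease
#' x territory, deaths per person), and the population-weighted exposure
#' `E`.  The product `P * AF * MR` reconstructs the baseline-deaths table
#' exactly, which is the invariant the decomposition relies on.
#'
#' @inheritParams attributableDeaths
#' @return named list (by year) of factor states.
#' @export
factorStates <- function(demography, deaths, exposure) {
  validateDeathsTable(deaths)
  if ("territory" %in% names(exposure) && !"scope" %in% names(exposure))
    exposure$scope <- exposure$territory
  years <- sort(unique(demography$year))
  terrs <- sort(unique(demography$territory))
  nA <- length(.ages); nD <- length(.diseases); nT <- length(terrs)
  ekey <- paste(exposure$scope, exposure$year)
  out <- lapply(years, function(y) {
    dem <- demography[demography$year == y, ]
    dth <- deaths[deaths$year == y, ]
    pop <- matrix(0, nA, nT, dimnames = list(.ages, terrs))
    pop[cbind(match(dem$age, .ages), match(dem$territory, terrs))] <-
      dem$population
    P <- colSums(pop)
    AF <- sweep(pop, 2, ifelse(P > 0, P, 1), "/")
    D <- array(0, c(nA, nD, nT), dimnames = list(.ages, .diseases, terrs))
    D[cbind(match(dth$age, .ages), match(dth$disease, .diseases),
            match(dth$territory, terrs))] <- dth$deaths
    MR <- D / array(ifelse(pop > 0, pop, 1)[rep(seq_len(nA), nD), ],
                    c(nA, nD, nT))
    E <- exposure$E[match(paste(terrs, y), ekey)]
    if (anyNA(E))
      stop(sprintf("exposure missing for year %s", y), call. = FALSE)
    list(year = y, territories = terrs, P = setNames(P, terrs), AF = AF,
         MR = MR, E = setNames(E, terrs))
  })
  names(out) <- as.character(years)
  out
}

# [age, disease, territory] array of PAF (or of its finite-difference
# sensitivity) at each territory's exposure; 0 on ineligible cells
pafFactorArray <- function(crfs, E, sens = FALSE, relDelta = 0.05,
                           clampLo = 1, clampHi = 5, variant = "central") {
  idx <- crfIndexTable(crfs)
  nA <- length(.ages); nD <- length(.diseases); nT <- length(E)
  out <- array(0, c(nA, nD, nT))
  for (u in unique(idx[!is.na(idx)])) {
    s <- crfs@.Data[[u]]
    cells <- which(idx == u)  # positions in the age x disease plane
    if (sens) {
      twoDelta <- clampValue(2 * relDelta * E, clampLo, clampHi)
      lo <- ifelse(E - twoDelta / 2 < 0, E, E - twoDelta / 2)
      hi <- lo + twoDelta
      vals <- (paf(s, hi, variant) - paf(s, lo, variant)) / twoDelta
    } else {
      vals <- paf(s, E, variant)
    }
    for (k in seq_len(nT))
      out[cells + (k - 1L) * nA * nD] <- vals[k]
  }
  out
}

# per-territory totals of AF * MR * PAF for one corner of the factor
# lattice; returns a named vector over territories
latticeTotals <- function(AF, MR, PAF) {
  nA <- dim(MR)[1]; nD <- dim(MR)[2]; nT <- dim(MR)[3]
  AFe <- aperm(array(AF, c(nA, nT, nD)), c(1, 3, 2))
  colSums(matrix(MR * PAF * AFe, nA * nD, nT))
}

#' Order-ensemble decomposition of one year pair
#'
#' Attributes the change in attributable deaths between two consecutive
#' factor states to the four drivers by averaging each driver's marginal
#' contribution over all 24 switching orderings (the Shapley value on the
#' four-factor lattice).  The four contributions sum to the total change
#' exactly, per territory.
#'
#' @param stateY,stateY1 two states from [factorStates()] (same
#'   territories).
#' @param crfs a [CRFSet-class].
#' @param type `"paf"` decomposes attributable deaths; `"sensitivity"`
#'   replaces PAF with its finite-difference exposure sensitivity, so the
#'   ledger decomposes the marginal benefit \eqn{\Delta D/\Delta E}.
#' @param relDelta,clampLo,clampHi finite-difference controls (used for
#'   `type = "sensitivity"`).
#' @return matrix (territories x 4 factors P, AF, MR, PAF) of
#'   contributions to the change; `attr(,"total")` holds the per-territory
#'   start/end totals.
#' @export
decomposePair <- function(stateY, stateY1, crfs,
                          type = c("paf", "sensitivity"),
                          relDelta = 0.05, clampLo = 1, clampHi = 5) {
  type <- match.arg(type)
  if (!identical(stateY$territories, stateY1$territories))
    stop("factor states cover different territories", call. = FALSE)
  if (!identical(dim(stateY$MR), dim(stateY1$MR)))
    stop("factor states have mismatched supports", call. = FALSE)
  sens <- type == "sensitivity"
  PAF0 <- pafFactorArray(crfs, stateY$E, sens, relDelta, clampLo, clampHi)
  PAF1 <- pafFactorArray(crfs, stateY1$E, sens, relDelta, clampLo, clampHi)
  AFs <- list(stateY$AF, stateY1$AF)
  MRs <- list(stateY$MR, stateY1$MR)
  PAFs <- list(PAF0, PAF1)
  Ps <- list(stateY$P, stateY1$P)
  # totals for all 8 (AF, MR, PAF) lattice corners, then all 16 states
  S <- array(list(), c(2, 2, 2))
  for (b in 1:2) for (cc in 1:2) for (d in 1:2)
    S[[b, cc, d]] <- latticeTotals(AFs[[b]], MRs[[cc]], PAFs[[d]])
  Dstate <- function(bits) Ps[[bits[1] + 1L]] *
    S[[bits[2] + 1L, bits[3] + 1L, bits[4] + 1L]]
  nT <- length(stateY$P)
  acc <- matrix(0, nT, 4, dimnames = list(stateY$territories, .factors))
  ords <- factorOrderings()
  for (t in seq_len(nrow(ords))) {
    bits <- c(P = 0L, AF = 0L, MR = 0L, PAF = 0L)
    prev <- Dstate(bits)
    for (f in ords[t, ]) {
      bits[f] <- 1L
      cur <- Dstate(bits)
      acc[, f] <- acc[, f] + (cur - prev)
      prev <- cur
    }
  }
  res <- acc / nrow(ords)
  attr(res, "total") <- cbind(start = Dstate(c(0L, 0L, 0L, 0L)),
                              end = Dstate(c(1L, 1L, 1L, 1L)))
  res
}

#' Chained decomposition of a yearly state sequence
#'
#' Applies [decomposePair()] to every pair of neighbouring years (to
#' minimize nonlinearity effects) and accumulates the per-factor
#' contributions relative to a pivot year: the ledger is zero at the
#' pivot, post-pivot years accumulate the forward pair sums, and
#' pre-pivot years carry the negated backward sums, so every entry reads
#' "change relative to the pivot".  The four cumulative factors sum to
#' the net change `D(y) - D(pivot)` exactly.
#'
#' @param states the [factorStates()] list (consecutive years).
#' @param crfs a [CRFSet-class].
#' @param pivotYear reference year inside the range.
#' @inheritParams decomposePair
#' @return long-format data.frame: scope (territory), year, factor,
#'   delta (pair contribution ending at `year`; `NA` for the first
#'   year), cumulative, net.  Attributes `baseline` (per scope-year
#'   totals of the decomposed quantity) and `pivotYear`.
#' @export
decomposeSeries <- function(states, crfs, pivotYear,
                            type = c("paf", "sensitivity"),
                            relDelta = 0.05, clampLo = 1, clampHi = 5) {
  type <- match.arg(type)
  years <- unname(vapply(states, `[[`, numeric(1), "year"))
  if (any(diff(years) != 1))
    stop("factor states must cover consecutive years", call. = FALSE)
  if (!pivotYear %in% years)
    stop("pivot year outside the state sequence", call. = FALSE)
  terrs <- states[[1]]$territories
  nT <- length(terrs); nY <- length(years)
  pair <- vector("list", nY - 1L)
  for (i in seq_len(nY - 1L))
    pair[[i]] <- decomposePair(states[[i]], states[[i + 1L]], crfs, type,
                               relDelta, clampLo, clampHi)
  totals <- vapply(seq_len(nY), function(i) {
    tt <- if (i < nY) attr(pair[[i]], "total")[, "start"]
          else attr(pair[[nY - 1L]], "total")[, "end"]
    tt
  }, numeric(nT))
  totals <- matrix(totals, nT, nY, dimnames = list(terrs, years))
  piv <- which(years == pivotYear)
  cum <- array(0, c(nT, nY, 4), dimnames = list(terrs, years, .factors))
  for (i in seq_len(nY)) {
    if (i > piv) {
      for (j in piv:(i - 1L)) cum[, i, ] <- cum[, i, ] + pair[[j]]
    } else if (i < piv) {
      for (j in i:(piv - 1L)) cum[, i, ] <- cum[, i, ] - pair[[j]]
    }
  }
  rows <- list()
  for (i in seq_len(nY)) for (f in .factors) {
    rows[[length(rows) + 1L]] <- data.frame(
      scope = terrs, year = years[i], factor = f,
      delta = if (i == 1L) NA_real_ else unname(pair[[i - 1L]][, f]),
      cumulative = unname(cum[, i, f]),
      net = unname(totals[, i] - totals[, piv]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- data.frame(
    scope = rep(terrs, nY), year = rep(years, each = nT),
    value = as.vector(totals))
  attr(out, "pivotYear") <- pivotYear
  out
}

#' @rdname decomposeSeries
#' @details `decomposeSensitivitySeries` is the same chained ensemble
#'   with the PAF factor replaced by its finite-difference exposure
#'   sensitivity, decomposing changes in the marginal benefit
#'   \eqn{\Delta D_{PM}/\Delta E}; its ledger is conventionally
#'   normalized to the pivot-year value after aggregation (see
#'   [aggregateLedger()]).
#' @export
decomposeSensitivitySeries <- function(states, crfs, pivotYear,
                                       relDelta = 0.05, clampLo = 1,
                                       clampHi = 5) {
  decomposeSeries(states, crfs, pivotYear, type = "sensitivity",
                  relDelta = relDelta, clampLo = clampLo,
                  clampHi = clampHi)
}

#' Aggregate a decomposition ledger over territories
#'
#' Sums the per-territory contributions (and the baseline totals) to
#' regions or the globe.  With `normalize = TRUE` every value is divided
#' by the scope's pivot-year baseline, turning the ledger into fractional
#' changes relative to the pivot — the conventional presentation for the
#' marginal-benefit decomposition.
#'
#' @param ledger a [decomposeSeries()] data.frame (with its attributes).
#' @param index a [TerritoryIndex-class].
#' @param level `"region"`, `"global"`, or `"territory"` (no grouping).
#' @param normalize divide by the scope's pivot-year baseline value.
#' @return aggregated ledger with the same columns; the `baseline`
#'   attribute is aggregated alongside.
#' @export
aggregateLedger <- function(ledger, index,
                            level = c("region", "global", "territory"),
                            normalize = FALSE) {
  level <- match.arg(level)
  base <- attr(ledger, "baseline")
  piv <- attr(ledger, "pivotYear")
  regions <- territoryRegions(index)
  grp <- switch(level,
                region = unname(regions[ledger$scope]),
                global = rep("global", nrow(ledger)),
                territory = ledger$scope)
  bgrp <- switch(level,
                 region = unname(regions[base$scope]),
                 global = rep("global", nrow(base)),
                 territory = base$scope)
  agg <- aggregate(ledger[c("delta", "cumulative", "net")],
                   list(scope = grp, year = ledger$year,
                        factor = ledger$factor),
                   function(x) if (all(is.na(x))) NA_real_ else sum(x))
  bagg <- aggregate(base["value"], list(scope = bgrp, year = base$year),
                    sum)
  if (normalize) {
    pv <- bagg$value[bagg$year == piv]
    names(pv) <- bagg$scope[bagg$year == piv]
    sc <- pv[agg$scope]
    if (any(sc == 0))
      stop("zero pivot-year baseline: cannot normalize", call. = FALSE)
    agg$delta <- agg$delta / sc
    agg$cumulative <- agg$cumulative / sc
    agg$net <- agg$net / sc
  }
  agg <- agg[order(agg$scope, agg$year, agg$factor), ]
  rownames(agg) <- NULL
  attr(agg, "baseline") <- bagg[order(bagg$scope, bagg$year), ]
  attr(agg, "pivotYear") <- piv
  agg
}
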