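# Shared fixtures and independent oracles for the test suite.

# small scenario that still exercises all stages
smallConfig <- function(...) {
  args <- list(nTerritories = 4L, nRegions = 2L, gridShape = c(12L, 12L),
               years = 1998:2009, breakpointYear = 2004L, noiseSd = 0.5,
               seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(scenarioConfig, args)
}

# disease-age eligibility, written out independently of the package
eligibleCell <- function(disease, age) {
  if (disease == "LRI") age < 5 || age >= 25 else age >= 25
}

allDiseases <- c("IHD", "Stroke", "COPD", "LC", "DM", "LRI")

# brute-force attributable deaths: plain double loop over table rows,
# evaluating each curve's RR directly from the closed form
bruteForceBurden <- function(deaths, EByTerritoryYear, crfs,
                             variant = "central") {
  tot <- 0
  for (r in seq_len(nrow(deaths))) {
    E <- EByTerritoryYear[[paste(deaths$territory[r], deaths$year[r])]]
    crf <- crfFor(crfs, deaths$disease[r], deaths$age[r])
    rr <- gemmRR(crf, E, variant)
    tot <- tot + deaths$deaths[r] * (1 - 1 / rr)
  }
  tot
}

# closed-form derivative of PAF(E) for a GEMM curve with explicit
# parameters: dPAF/dE = theta f'(z) / RR(E), z = E - zcf (assumes E > zcf)
analyticGemmPafDeriv <- function(theta, alpha, mu, nu, zcf, E) {
  z <- E - zcf
  g <- log1p(z / alpha)
  s <- 1 / (1 + exp(-(z - mu) / nu))
  fp <- s / (alpha + z) + g * s * (1 - s) / nu
  rr <- exp(theta * g * s)
  theta * fp / rr
}

# random full-dimension factor state for two territories
randomFactorState <- function(year, scale = 1) {
  ages <- 0:95
  terrs <- c("A", "B")
  nA <- length(ages); nD <- length(allDiseases)
  P <- setNames(runif(2, 1e5, 1e6) * scale, terrs)
  w <- matrix(runif(nA * 2, 0.2, 1), nA, 2,
              dimnames = list(ages, terrs))
  AF <- sweep(w, 2, colSums(w), "/")
  MR <- array(0, c(nA, nD, 2), dimnames = list(ages, allDiseases, terrs))
  for (j in seq_len(nD)) for (i in seq_len(nA)) {
    if (eligibleCell(allDiseases[j], ages[i]))
      MR[i, j, ] <- runif(2, 0, 2e-3)
  }
  E <- setNames(runif(2, 5, 80), terrs)
  list(year = year, territories = terrs, P = P, AF = AF, MR = MR, E = E)
}

# independent total attributable deaths for a (possibly mixed) state:
# per-cell loops with RR evaluated through the public scalar interface
stateTotalOracle <- function(P, AF, MR, E, crfs) {
  ages <- as.integer(rownames(AF))
  tot <- setNames(numeric(length(P)), names(P))
  pafCache <- list()
  for (k in seq_along(P)) {
    for (j in seq_along(allDiseases)) {
      dis <- allDiseases[j]
      for (i in seq_along(ages)) {
        if (MR[i, j, k] == 0) next
        key <- paste(dis, ages[i], E[k])
        if (is.null(pafCache[[key]])) {
          rr <- gemmRR(crfFor(crfs, dis, ages[i]), E[k])
          pafCache[[key]] <- 1 - 1 / rr
        }
        tot[k] <- tot[k] + P[k] * AF[i, k] * MR[i, j, k] * pafCache[[key]]
      }
    }
  }
  tot
}

# brute-force Shapley values over the 2^4 coalition lattice
shapleyOracle <- function(s0, s1, crfs) {
  factors <- c("P", "AF", "MR", "PAF")
  val <- function(subset) {
    P <- if ("P" %in% subset) s1$P else s0$P
    AF <- if ("AF" %in% subset) s1$AF else s0$AF
    MR <- if ("MR" %in% subset) s1$MR else s0$MR
    E <- if ("PAF" %in% subset) s1$E else s0$E
    sum(stateTotalOracle(P, AF, MR, E, crfs))
  }
  out <- setNames(numeric(4), factors)
  others <- function(f) setdiff(factors, f)
  for (f in factors) {
    rest <- others(f)
    for (sz in 0:3) {
      subsets <- if (sz == 0) list(character(0))
                 else apply(combn(rest, sz), 2, identity, simplify = FALSE)
      wgt <- factorial(sz) * factorial(4 - sz - 1) / factorial(4)
      for (S in subsets)
        out[f] <- out[f] + wgt * (val(c(S, f)) - val(S))
    }
  }
  out
}
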