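#' Construct a single GEMM-form concentration-response curve
#'
#' @param disease one of IHD, Stroke, COPD, LC, DM, LRI.
#' @param ageLo,ageHi inclusive age band (use `Inf` for open-ended).
#' @param theta central log-hazard scale parameter; the 95% band is
#'   `thetaLower`/`thetaUpper` (defaults +/-20% of central).
#' @param thetaLower,thetaUpper lower/upper variants of `theta`.
#' @param alpha,mu,nu GEMM shape parameters; `alpha` and `nu` positive.
#' @param zCf counterfactual concentration (theoretical minimum-risk
#'   exposure level) in \eqn{\mu g/m^3}.
#' @return a [CRFSpec-class].
#' @export
crfSpec <- function(disease, ageLo, ageHi, theta,
                    thetaLower = 0.8 * theta, thetaUpper = 1.2 * theta,
                    alpha, mu, nu, zCf = 2.4) {
  new("CRFSpec", disease = disease,
      ageLo = as.numeric(ageLo), ageHi = as.numeric(ageHi),
      theta = c(lower = thetaLower, central = theta, upper = thetaUpper),
      alpha = alpha, mu = mu, nu = nu, zCf = zCf)
}

setMethod("show", "CRFSpec", function(object) {
  cat(sprintf("CRFSpec %s ages %g-%g: theta %.4f [%.4f, %.4f], alpha %.2f, mu %.2f, nu %.2f, zCf %.1f\n",
              object@disease, object@ageLo, object@ageHi,
              object@theta["central"], object@theta["lower"],
              object@theta["upper"], object@alpha, object@mu, object@nu,
              object@zCf))
})

setMethod("show", "CRFSet", function(object) {
  ds <- vapply(object@.Data, function(x) x@disease, character(1))
  cat(sprintf("CRFSet: %d curves (%s)\n", length(object),
              paste(sprintf("%s:%d", names(table(ds)), table(ds)),
                    collapse = ", ")))
})

#' Built-in GEMM-form concentration-response parameter set
#'
#' A complete fixture parameter set covering every eligible (disease, age)
#' combination: age-resolved curves in 5-year bands from 25-29 to 95+ for
#' IHD and Stroke (hazard scale declining with age, as cardiovascular
#' relative risks attenuate in the oldest groups), one age-independent
#' curve each for COPD, lung cancer and diabetes (ages 25+), and LRI
#' curves for both eligible windows (under 5, and 25+).  The shape
#' parameters give supra-linear curves that keep rising but flatten at
#' high concentration, so the attributable-fraction sensitivity is larger
#' at low exposure.  These are synthetic stand-in values with realistic
#' magnitudes, not estimates from any cohort.
#'
#' @param zCf counterfactual concentration (\eqn{\mu g/m^3}) at which all
#'   curves are anchored to relative risk 1.
#' @return a [CRFSet-class].
#' @examples
#' crfs <- defaultCRFParameters()
#' gemmRR(crfFor(crfs, "IHD", 60), E = 50)
#' @export
defaultCRFParameters <- function(zCf = 2.4) {
  specs <- list()
  bands <- seq(25, 95, by = 5)
  for (b in seq_along(bands)) {
    lo <- bands[b]
    hi <- if (lo == 95) Inf else lo + 4
    specs[[length(specs) + 1L]] <- crfSpec(
      "IHD", lo, hi, theta = 0.32 - 0.014 * (b - 1),
      alpha = 1.9, mu = 12.0, nu = 40.2, zCf = zCf)
    specs[[length(specs) + 1L]] <- crfSpec(
      "Stroke", lo, hi, theta = 0.28 - 0.012 * (b - 1),
      alpha = 6.2, mu = 16.7, nu = 23.7, zCf = zCf)
  }
  specs[[length(specs) + 1L]] <-
    crfSpec("COPD", 25, Inf, theta = 0.16, alpha = 6.5, mu = 2.5,
            nu = 32.0, zCf = zCf)
  specs[[length(specs) + 1L]] <-
    crfSpec("LC", 25, Inf, theta = 0.15, alpha = 6.2, mu = 9.3,
            nu = 29.8, zCf = zCf)
  specs[[length(specs) + 1L]] <-
    crfSpec("DM", 25, Inf, theta = 0.18, alpha = 5.2, mu = 8.4,
            nu = 35.0, zCf = zCf)
  specs[[length(specs) + 1L]] <-
    crfSpec("LRI", 0, 4, theta = 0.22, alpha = 6.4, mu = 5.7,
            nu = 8.7, zCf = zCf)
  specs[[length(specs) + 1L]] <-
    crfSpec("LRI", 25, Inf, theta = 0.22, alpha = 6.4, mu = 5.7,
            nu = 8.7, zCf = zCf)
  new("CRFSet", specs)
}

#' Look up the curve covering a (disease, age) cell
#'
#' @param crfs a [CRFSet-class].
#' @param disease disease code.
#' @param age single-year age; mapped into the curve's age band.
#' @return the matching [CRFSpec-class]; error if none covers the cell.
#' @export
crfFor <- function(crfs, disease, age) {
  for (s in crfs@.Data) {
    if (s@disease == disease && age >= s@ageLo && age <= s@ageHi)
      return(s)
  }
  stop(sprintf("no concentration-response curve for %s at age %s",
               disease, age), call. = FALSE)
}

#' Evaluate a GEMM-form relative risk
#'
#' \deqn{RR(E) = \exp\left(\theta\,\frac{\log(1 + z/\alpha)}
#'   {1 + \exp(-(z - \mu)/\nu)}\right), \qquad z = \max(0, E - z_{cf}).}
#' The curve equals 1 at and below the counterfactual concentration and is
#' monotone non-decreasing above it.
#'
#' @param crf a [CRFSpec-class].
#' @param E exposure concentration(s) in \eqn{\mu g/m^3}, non-negative.
#' @param variant which parameter variant to evaluate: `"central"`
#'   (default), `"lower"` or `"upper"` bound of the 95% band.
#' @return numeric vector of relative risks, same length as `E`.
#' @examples
#' crf <- crfSpec("COPD", 25, Inf, theta = 0.16, alpha = 6.5,
#'                mu = 2.5, nu = 32)
#' gemmRR(crf, c(2.4, 10, 50))
#' @export
gemmRR <- function(crf, E, variant = c("central", "lower", "upper")) {
  variant <- match.arg(variant)
  if (any(E < 0)) stop("exposure must be non-negative", call. = FALSE)
  if (crf@alpha <= 0 || crf@nu <= 0)
    stop("alpha and nu must be positive", call. = FALSE)
  z <- pmax(0, E - crf@zCf)
  th <- crf@theta[[variant]]
  exp(th * log1p(z / crf@alpha) / (1 + exp(-(z - crf@mu) / crf@nu)))
}

#' Population attributable fraction of a curve at an exposure
#'
#' \eqn{PAF(E) = 1 - 1/RR(E)}: the fraction of baseline deaths in the
#' curve's (disease, age) cell attributable to exposure above the
#' counterfactual.  Lies in `[0, 1)` and increases wherever RR does.
#'
#' @inheritParams gemmRR
#' @return numeric vector of attributable fractions.
#' @export
paf <- function(crf, E, variant = c("central", "lower", "upper")) {
  rr <- gemmRR(crf, E, variant)
  if (any(rr < 1 - 1e-12))
    stop("relative risk below 1: malformed concentration-response curve",
         call. = FALSE)
  1 - 1 / rr
}

#' Read or write a CRF parameter table as CSV
#'
#' Columns: disease, age_lo, age_hi, theta_lower, theta, theta_upper,
#' alpha, mu, nu, z_cf.  Open-ended bands use `Inf` for age_hi.
#'
#' @param crfs a [CRFSet-class].
#' @param path CSV path.
#' @return `readCRFTable` returns a [CRFSet-class]; `writeCRFTable`
#'   returns `path` invisibly.
#' @export
writeCRFTable <- function(crfs, path) {
  rows <- lapply(crfs@.Data, function(s) data.frame(
    disease = s@disease, age_lo = s@ageLo, age_hi = s@ageHi,
    theta_lower = s@theta[["lower"]], theta = s@theta[["central"]],
    theta_upper = s@theta[["upper"]], alpha = s@alpha, mu = s@mu,
    nu = s@nu, z_cf = s@zCf))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCRFTable
#' @export
readCRFTable <- function(path) {
  tb <- read.csv(path)
  specs <- lapply(seq_len(nrow(tb)), function(i) crfSpec(
    disease = tb$disease[i], ageLo = tb$age_lo[i], ageHi = tb$age_hi[i],
    theta = tb$theta[i], thetaLower = tb$theta_lower[i],
    thetaUpper = tb$theta_upper[i], alpha = tb$alpha[i], mu = tb$mu[i],
    nu = tb$nu[i], zCf = tb$z_cf[i]))
  new("CRFSet", specs)
}
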