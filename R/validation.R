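#' Root mean square difference between estimates and observations
#'
#' \deqn{RMSD = \sqrt{\sum_s (x^s_{est} - x^s_{obs})^2 / n}}
#'
#' @param est,obs numeric vectors of collocated estimates and
#'   observations (same length, n >= 1).
#' @return RMSD in the units of the inputs.
#' @examples
#' rmsd(c(10, 20), c(12, 18))  # 2
#' @export
rmsd <- function(est, obs) {
  if (length(est) != length(obs))
    stop("est and obs must have the same length", call. = FALSE)
  if (length(est) == 0L) stop("empty input", call. = FALSE)
  sqrt(mean((est - obs)^2))
}

#' Normalized root mean square difference
#'
#' [rmsd()] divided by the mean of the observations; dimensionless and
#' invariant to a common rescaling of both series.
#'
#' @inheritParams rmsd
#' @return dimensionless NRMSD.
#' @export
nrmsd <- function(est, obs) {
  m <- mean(obs)
  if (!(m > 0))
    stop("mean of observations must be positive", call. = FALSE)
  rmsd(est, obs) / m
}

#' Bootstrapped NRMSD of population-weighted exposure versus sample size
#'
#' Evaluates how well population-weighted exposure computed from a
#' network of monitoring sites agrees between observations and collocated
#' estimates, as a function of the number of sites used.  For each draw
#' size `n`, sites are sampled without replacement `m = round(N/n * 200)`
#' times (`N` = total sites); each draw yields a pair of
#' population-weighted means (observed, estimated), and the NRMSD across
#' the `m` pairs is reported.  At `n = N` every draw is the full network,
#' so the spread across draws vanishes and the NRMSD reduces to the
#' single deterministic comparison.
#'
#' @param monitors data.frame with columns `obs`, `est` (annual-mean
#'   concentrations, \eqn{\mu g/m^3}) and `population` (weight of the
#'   raster cell containing each site).
#' @param nSites integer vector of draw sizes (each <= number of sites).
#' @param seed integer seed making the draws reproducible.
#' @return data.frame with columns n, m, nrmsd.
#' @export
bootstrapPwNrmsd <- function(monitors, nSites, seed = 1L) {
  need <- c("obs", "est", "population")
  miss <- setdiff(need, names(monitors))
  if (length(miss))
    stop("monitors table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  N <- nrow(monitors)
  if (any(nSites > N))
    stop("draw size exceeds the number of sites", call. = FALSE)
  if (any(monitors$population <= 0))
    stop("site populations must be positive", call. = FALSE)
  set.seed(seed)
  rows <- lapply(nSites, function(n) {
    m <- max(1L, as.integer(round(N / n * 200)))
    pw <- vapply(seq_len(m), function(i) {
      s <- sample.int(N, n, replace = FALSE)
      w <- monitors$population[s]
      c(sum(monitors$obs[s] * w), sum(monitors$est[s] * w)) / sum(w)
    }, numeric(2))
    data.frame(n = n, m = m, nrmsd = nrmsd(pw[2, ], pw[1, ]))
  })
  do.call(rbind, rows)
}
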