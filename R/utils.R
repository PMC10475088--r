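# Internal helpers shared across modules.

#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats lm coef confint pnorm pt qt median rnorm runif uniroot
#'   setNames aggregate cor sd
#' @importFrom utils read.csv write.csv packageVersion combn
NULL

# recycle a scalar to length n; length-n vectors pass through
recycleTerr <- function(x, n, what) {
  if (length(x) == 1L) return(rep(as.numeric(x), n))
  if (length(x) == n) return(as.numeric(x))
  stop(sprintf("'%s' must have length 1 or %d, got %d", what, n, length(x)),
       call. = FALSE)
}

clampValue <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# deterministic substream seed derived from a master seed; kept within
# 32-bit integer range whatever the master seed is
substreamSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %%
               2147483647)
}

# eligibility of a (disease, age) cell for PM2.5-attributable mortality:
# LRI applies to children under 5 and adults 25+, the other five diseases
# to adults 25+ only
isEligibleAge <- function(disease, age) {
  ifelse(disease == "LRI", age < 5 | age >= 25, age >= 25)
}

eligibleAges <- function(disease) {
  if (disease == "LRI") c(0:4, 25:95) else 25:95
}

stopifnotYears <- function(years) {
  if (length(years) < 3L)
    stop("need at least 3 years", call. = FALSE)
  if (any(diff(years) != 1L))
    stop("years must be consecutive", call. = FALSE)
}
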