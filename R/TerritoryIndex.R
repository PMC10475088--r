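#' Construct a TerritoryIndex
#'
#' @param codes integer matrix of per-cell territory indices (`NA` for
#'   cells outside every territory).
#' @param territories character vector of territory identifiers.
#' @param regions character vector assigning each territory to a region.
#' @return a [TerritoryIndex-class].
#' @export
territoryIndex <- function(codes, territories, regions) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  new("TerritoryIndex", codes = codes,
      territories = as.character(territories), regions = as.character(regions))
}

#' Accessors for TerritoryIndex
#'
#' `territoryNames` lists the territory identifiers, `regionNames` the
#' distinct regions, and `territoryRegions` the territory-to-region map
#' as a named character vector.
#'
#' @param x a [TerritoryIndex-class].
#' @return character vectors as described.
#' @export
territoryNames <- function(x) x@territories

#' @rdname territoryNames
#' @export
regionNames <- function(x) unique(x@regions)

#' @rdname territoryNames
#' @export
territoryRegions <- function(x) stats::setNames(x@regions, x@territories)

setMethod("show", "TerritoryIndex", function(object) {
  cat(sprintf("TerritoryIndex: %d territories in %d regions over %d x %d cells\n",
              length(object@territories), length(unique(object@regions)),
              nrow(object@codes), ncol(object@codes)))
  cat(sprintf("  %d cells unassigned (NA)\n", sum(is.na(object@codes))))
})

# logical matrix selecting cells of a scope; scope is "global", a region
# name, or a vector of territory identifiers
scopeMask <- function(index, scope) {
  codes <- index@codes
  if (identical(scope, "global"))
    return(!is.na(codes))
  if (length(scope) == 1L && scope %in% index@regions) {
    keep <- which(index@regions == scope)
  } else {
    keep <- match(scope, index@territories)
    if (anyNA(keep))
      stop(sprintf("unknown scope: %s",
                   paste(scope[is.na(keep)], collapse = ", ")), call. = FALSE)
  }
  !is.na(codes) & matrix(codes %in% keep, nrow(codes), ncol(codes))
}
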