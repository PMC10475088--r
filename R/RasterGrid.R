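#' Construct a RasterGrid
#'
#' @param values numeric matrix of cell values (rows = latitude, columns =
#'   longitude); `NA` marks nodata cells.
#' @param resolution cell size in degrees.
#' @param origin numeric `c(lat, lon)` of the lower-left *corner* of the
#'   grid; cell centers are offset by half a cell.
#' @return a [RasterGrid-class] object.
#' @examples
#' rg <- rasterGrid(matrix(1:12, 3, 4), resolution = 0.5)
#' gridValues(rg)[1, 1]
#' @export
rasterGrid <- function(values, resolution, origin = c(0, 0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  lat <- origin[1] + (seq_len(nrow(values)) - 0.5) * resolution
  lon <- origin[2] + (seq_len(ncol(values)) - 0.5) * resolution
  new("RasterGrid", values = values, lat = lat, lon = lon,
      resolution = resolution)
}

#' @rdname rasterGrid
#' @param x a `RasterGrid`.
#' @export
gridValues <- function(x) x@values

#' @rdname rasterGrid
#' @export
gridLat <- function(x) x@lat

#' @rdname rasterGrid
#' @export
gridLon <- function(x) x@lon

#' @rdname rasterGrid
#' @export
gridResolution <- function(x) x@resolution

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid: %d x %d cells at %g deg\n",
              nrow(v), ncol(v), object@resolution))
  cat(sprintf("  lat %.3f..%.3f, lon %.3f..%.3f\n",
              min(object@lat), max(object@lat),
              min(object@lon), max(object@lon)))
  cat(sprintf("  values: min %.4g, mean %.4g, max %.4g, %d NA\n",
              min(v, na.rm = TRUE), mean(v, na.rm = TRUE),
              max(v, na.rm = TRUE), sum(is.na(v))))
})

# two rasters live on the same grid?
sameGrid <- function(a, b, tol = 1e-9) {
  identical(dim(a@values), dim(b@values)) &&
    isTRUE(all.equal(a@lat, b@lat, tolerance = tol)) &&
    isTRUE(all.equal(a@lon, b@lon, tolerance = tol))
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange in the ESRI ASCII grid (`.asc`) format:
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows of cell values ordered
#' north to south.
#'
#' @param x a [RasterGrid-class] (for writing).
#' @param path file path.
#' @param nodata value written in place of `NA` cells.
#' @return `readAsciiGrid` returns a [RasterGrid-class];
#'   `writeAsciiGrid` returns `path` invisibly.
#' @examples
#' rg <- rasterGrid(matrix(runif(12), 3, 4), resolution = 0.1)
#' f <- tempfile(fileext = ".asc")
#' writeAsciiGrid(rg, f)
#' rg2 <- readAsciiGrid(f)
#' all.equal(gridValues(rg), gridValues(rg2))
#' @export
writeAsciiGrid <- function(x, path, nodata = -9999) {
  v <- x@values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", min(x@lon) - x@resolution / 2),
    sprintf("yllcorner %.10g", min(x@lat) - x@resolution / 2),
    sprintf("cellsize %.10g", x@resolution),
    sprintf("NODATA_value %.10g", nodata))
  v[is.na(v)] <- nodata
  # rows are written from the northernmost latitude downwards
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1L,
                function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, character(1), 1L))
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2L))
  names(vals) <- keys
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  body <- lapply(lines[7:(6 + nr)],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  v <- do.call(rbind, body)
  stopifnot(ncol(v) == nc, nrow(v) == nr)
  v[v == vals[["nodata_value"]]] <- NA_real_
  rasterGrid(v[rev(seq_len(nr)), , drop = FALSE],
             resolution = vals[["cellsize"]],
             origin = c(vals[["yllcorner"]], vals[["xllcorner"]]))
}
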