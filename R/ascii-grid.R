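# ESRI ASCII grid backend.
#
# All rasters handled by the package (scene bands, cloud masks, pond masks,
# classified labels) are stored as ESRI ASCII grids (.asc), a plain-text
# single-band raster format readable by standard GIS software. I/O is
# delegated to the sp package. Matrices follow map orientation: row 1 is the
# northernmost (top) raster row.

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file.
#' @return a list with `values` (numeric matrix, row 1 = top row), `xll`,
#'   `yll` (lower-left corner coordinates), `cellsize` (m) and `nodata`
#'   cells returned as `NA`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) {
    stop_pond("pond_io_error", "cannot read raster: %s", path)
  }
  g <- tryCatch(sp::read.asciigrid(path),
                error = function(e) stop_pond("pond_io_error",
                                              "failed to parse ASCII grid %s: %s",
                                              path, conditionMessage(e)))
  dims <- g@grid@cells.dim              # (ncols, nrows)
  vals <- matrix(g@data[[1L]], nrow = dims[2L], ncol = dims[1L], byrow = TRUE)
  cs <- g@grid@cellsize
  ll <- g@grid@cellcentre.offset - cs / 2
  list(values = vals, xll = ll[[1L]], yll = ll[[2L]], cellsize = cs[[1L]])
}

#' Write an ESRI ASCII grid
#'
#' @param values numeric matrix, row 1 = top (northernmost) row.
#' @param path output path.
#' @param xll,yll lower-left corner coordinates.
#' @param cellsize cell edge length in metres (pixels are square).
#' @param na_value sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(values, path, xll = 0, yll = 0, cellsize = 30,
                             na_value = -9999) {
  if (!is.matrix(values)) stop_pond("pond_input_error", "values must be a matrix")
  gt <- sp::GridTopology(c(xll + cellsize / 2, yll + cellsize / 2),
                         c(cellsize, cellsize),
                         c(ncol(values), nrow(values)))
  sgdf <- sp::SpatialGridDataFrame(gt, data.frame(z = as.vector(t(values))))
  ok <- tryCatch({ sp::write.asciigrid(sgdf, path, na.value = na_value); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_pond("pond_io_error", "cannot write raster: %s", path)
  invisible(path)
}
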