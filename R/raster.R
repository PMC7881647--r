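## Lightweight gridded-surface container.  The study's covariate and population
## surfaces arrive as single-band rasters; here they are square-pixel grids
## in planar km with an ESRI-ASCII-like plain-text serialization.

#' Create a gridded surface
#'
#' A minimal single-band raster: a numeric matrix of pixel values on a regular
#' square grid in planar km.  Row 1 of `values` is the *southernmost* row
#' (y increases with row index); column 1 is the westernmost column.
#'
#' @param values numeric matrix of pixel values (`NA` = nodata).
#' @param xmin,ymin coordinates (km) of the lower-left corner of the grid.
#' @param res pixel side length in km (> 0).
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, res = 1) {
  stop_if_not_scalar_pos(res, "res")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  structure(list(values = values, xmin = xmin, ymin = ymin, res = res),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d pixels, res %g km, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$res, x$xmin, x$ymin))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Pixel-center coordinates of a gridded surface
#' @param r a `grid_raster`.
#' @return Two-column matrix (x, y) in row-major order matching `as.vector(r$values)`.
#' @export
raster_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  xs <- r$xmin + (seq_len(nc) - 0.5) * r$res
  ys <- r$ymin + (seq_len(nr) - 0.5) * r$res
  cbind(x = rep(xs, each = nr), y = rep(ys, times = nc))
}

#' Write / read a gridded surface as plain text
#'
#' Serialization is a small header (ncols, nrows, xmin, ymin, res, nodata)
#' followed by rows of values, north to south, mirroring the classic ASCII
#' grid layout so files are diffable and tool-independent.
#'
#' @param r a `grid_raster`.
#' @param path file path.
#' @return `read_grid_raster` returns a `grid_raster`.
#' @export
write_grid_raster <- function(r, path) {
  stopifnot(inherits(r, "grid_raster"))
  v <- r$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", format(r$xmin, digits = 17)),
    paste("yllcorner", format(r$ymin, digits = 17)),
    paste("cellsize", format(r$res, digits = 17)),
    "nodata_value -9999"), con)
  for (i in rev(seq_len(nrow(v)))) {
    row <- v[i, ]
    row[is.na(row)] <- -9999
    writeLines(paste(format(row, digits = 17, trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_grid_raster
#' @export
read_grid_raster <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  get <- function(key) as.numeric(sub(paste0("^", key, "\\s+"), "", hdr[grepl(paste0("^", key), hdr)]))
  nc <- get("ncols"); nr <- get("nrows")
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]          # back to south-first rows
  m[m == get("nodata_value")] <- NA_real_
  grid_raster(m, xmin = get("xllcorner"), ymin = get("yllcorner"), res = get("cellsize"))
}

## nearest pixel index for a coordinate along one axis; ties on a pixel
## boundary resolve to the LOWER index (deterministic contract)
nearest_pixel_index <- function(coord, origin, res, nmax) {
  u <- (coord - origin) / res
  idx <- floor(u) + 1
  on_edge <- abs(u - round(u)) < 1e-9 & round(u) >= 1
  idx[on_edge] <- round(u[on_edge])                 # boundary -> lower pixel
  pmin(pmax(idx, 1), nmax)
}
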