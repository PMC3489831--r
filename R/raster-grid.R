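#' Matrix-backed single-band raster
#'
#' A minimal in-memory raster: a numeric (or integer) matrix plus grid
#' metadata in a projected coordinate system (metres). Row 1 is the north
#' edge of the grid; column 1 the west edge. Cell membership uses half-open
#' intervals `[x0, x0 + cellsize)` so a point on a shared cell edge belongs
#' to exactly one cell. Missing data are `NA`.
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xmin,ymin coordinates (m) of the grid's lower-left corner.
#' @param cellsize cell edge length in metres.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cellsize = 30) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<raster_grid> %d x %d cells @ %g m, origin (%g, %g)\n",
    nrow(v), ncol(v), x$cellsize, x$xmin, x$ymin
  ))
  fin <- v[is.finite(v)]
  if (length(fin)) {
    cat(sprintf("  values: [%g, %g], %d NA\n",
                min(fin), max(fin), sum(is.na(v))))
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

rg_xmax <- function(g) g$xmin + ncol(g$values) * g$cellsize
rg_ymax <- function(g) g$ymin + nrow(g$values) * g$cellsize

#' Row/column indices of the cells containing points
#'
#' Points outside the grid extent get `NA` indices.
#'
#' @param grid a [raster_grid()].
#' @param x,y point coordinates (m).
#' @return data.frame with columns `row`, `col`.
#' @export
rg_cell <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cellsize
  col <- floor((x - grid$xmin) / cs) + 1L
  row <- nr - floor((y - grid$ymin) / cs)
  bad <- !is.finite(x) | !is.finite(y) |
    col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' @inheritParams rg_cell
#' @return vector of cell values (`NA` outside the extent).
#' @export
rg_extract <- function(grid, x, y) {
  rc <- rg_cell(grid, x, y)
  out <- rep(grid$values[1][NA], length(x))
  ok <- !is.na(rc$row)
  out[ok] <- grid$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Cell-centre coordinates of every cell
#'
#' @param grid a [raster_grid()].
#' @return list with matrices `x` and `y`, same shape as the values.
#' @export
rg_coords <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cellsize
  xs <- grid$xmin + (seq_len(nc) - 0.5) * cs
  ys <- grid$ymin + (nr - seq_len(nr) + 0.5) * cs
  list(
    x = matrix(xs, nr, nc, byrow = TRUE),
    y = matrix(ys, nr, nc)
  )
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Plain-text interchange format; `NA` written as the nodata value.
#'
#' @param grid a [raster_grid()].
#' @param path output file path.
#' @param nodata numeric nodata sentinel.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  v[is.na(v)] <- nodata
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path input file path.
#' @return a [raster_grid()] with nodata cells set to `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows"); nodata <- val("NODATA_value")
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  v <- t(vapply(body, function(r) as.numeric(r), numeric(nc)))
  stopifnot(nrow(v) == nr)
  v[v == nodata] <- NA
  raster_grid(v, xmin = val("xllcorner"), ymin = val("yllcorner"),
              cellsize = val("cellsize"))
}
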