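#' Grid raster objects
#'
#' A minimal in-memory raster: a numeric matrix with a square-cell
#' georeference.  Row 1 is the northern edge of the grid; cell centres are at
#' `xll + (col - 0.5) * cell_size`, `yll + (nrow - row + 0.5) * cell_size`.
#' Values may be numeric or logical; `NA` encodes nodata.
#'
#' @param values numeric or logical matrix (rows = north to south).
#' @param cell_size side length of a cell in meters (> 0).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @return An object of class `hn_raster`.
#' @export
hn_raster <- function(values, cell_size, xll = 0, yll = 0) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  structure(
    list(values = values, cell_size = cell_size,
         xll = as.numeric(xll), yll = as.numeric(yll)),
    class = "hn_raster"
  )
}

#' @export
print.hn_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<hn_raster> %d x %d cells, cell_size %g m\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xll, x$xll + ncol(x$values) * x$cell_size,
              x$yll, x$yll + nrow(x$values) * x$cell_size))
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d nodata\n", min(v), max(v),
                sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.hn_raster <- function(x) dim(x$values)

is_hn_raster <- function(x) inherits(x, "hn_raster")

#' Check that two rasters share shape and georeference
#' @noRd
check_aligned <- function(a, b, what = "rasters") {
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(a$cell_size, b$cell_size)) ||
      !isTRUE(all.equal(c(a$xll, a$yll), c(b$xll, b$yll))))
    stop(sprintf("misaligned %s: shape, cell size and origin must match", what))
  invisible(TRUE)
}

#' Cell centre coordinates for linear cell indices
#'
#' @param r an `hn_raster`.
#' @param cells integer vector of linear (column-major) cell indices; default
#'   all cells.
#' @return A two-column matrix of x, y cell-centre coordinates.
#' @export
cell_xy <- function(r, cells = seq_len(length(r$values))) {
  nr <- nrow(r$values)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  cbind(x = r$xll + (col - 0.5) * r$cell_size,
        y = r$yll + (nr - row + 0.5) * r$cell_size)
}

#' Linear cell index containing each point
#'
#' Points outside the grid map to `NA`.  Points exactly on the eastern or
#' northern boundary are assigned to the last cell.
#'
#' @param r an `hn_raster`.
#' @param x,y point coordinates.
#' @return Integer vector of linear cell indices (`NA` if outside).
#' @export
cell_at_xy <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  col <- floor((x - r$xll) / cs) + 1L
  rowfb <- floor((y - r$yll) / cs) + 1L   # row counted from the bottom
  col[x == r$xll + nc * cs] <- nc
  rowfb[y == r$yll + nr * cs] <- nr
  row <- nr - rowfb + 1L
  ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
  out <- rep(NA_integer_, length(col))
  out[ok] <- (col[ok] - 1L) * nr + row[ok]
  out
}

#' Read and write Esri ASCII grid files
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values from north to south.
#'
#' @param r an `hn_raster`.
#' @param path file path (conventionally `.asc`).
#' @param nodata value used to encode `NA` on disk.
#' @return `write_asc` returns `path` invisibly; `read_asc` returns an
#'   `hn_raster`.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  stopifnot(is_hn_raster(r))
  v <- r$values
  storage.mode(v) <- "double"
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  rows <- apply(v, 1L, function(z) paste(formatC(z, format = "g", digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(
    vapply(kv, function(x) as.numeric(x[2L]), numeric(1)),
    tolower(vapply(kv, `[`, character(1), 1L))
  )
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  nc <- as.integer(hdr[["ncols"]]); nr <- as.integer(hdr[["nrows"]])
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr[["nodata_value"]]] <- NA_real_
  hn_raster(m, cell_size = hdr[["cellsize"]],
            xll = hdr[["xllcorner"]], yll = hdr[["yllcorner"]])
}
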