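# Plain-text georeferenced grids (ESRI ASCII grid dialect) and
# resolution aggregation.

#' Construct a georeferenced grid
#'
#' A minimal in-memory raster: a numeric matrix (row 1 = northernmost
#' row, as in the ESRI ASCII grid format) plus the lower-left corner and
#' the square cell size. `NA` cells are masked.
#'
#' @param data Numeric matrix.
#' @param xll,yll Coordinates of the lower-left corner of the grid (m).
#' @param cellsize Cell edge length (m).
#' @return An object of class `ascii_grid`.
#' @export
ascii_grid <- function(data, xll = 0, yll = 0, cellsize = 1500) {
  stopifnot(is.matrix(data), cellsize > 0)
  structure(list(data = data, xll = xll, yll = yll, cellsize = cellsize),
            class = "ascii_grid")
}

#' @export
print.ascii_grid <- function(x, ...) {
  cat("ascii_grid: ", nrow(x$data), " rows x ", ncol(x$data),
      " cols, cellsize ", x$cellsize, " m, origin (", x$xll, ", ",
      x$yll, ")\n", sep = "")
  cat("  values: ", sum(!is.na(x$data)), " unmasked, range ",
      paste(signif(range(x$data, na.rm = TRUE), 5), collapse = " to "),
      "\n", sep = "")
  invisible(x)
}

#' Write a grid as an ESRI ASCII raster
#'
#' @param grid An [ascii_grid()].
#' @param path Output file path (conventionally `.asc`).
#' @param digits Significant digits for cell values.
#' @param nodata Value written for masked cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, digits = 10, nodata = -9999) {
  stopifnot(inherits(grid, "ascii_grid"))
  d <- grid$data
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(d)),
               paste("nrows", nrow(d)),
               paste("xllcorner", format(grid$xll, scientific = FALSE)),
               paste("yllcorner", format(grid$yll, scientific = FALSE)),
               paste("cellsize", format(grid$cellsize, scientific = FALSE)),
               paste("NODATA_value", nodata)), con)
  vals <- signif(d, digits)
  vals[is.na(vals)] <- nodata
  writeLines(apply(vals, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path File written by [write_ascii_grid()] or any conforming
#'   ASCII grid.
#' @return An [ascii_grid()]; NODATA cells are `NA`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  keys <- vapply(hdr, `[`, character(1), 1L)
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  body <- lines[-(1:6)]
  cells <- scan(text = body, quiet = TRUE)
  d <- matrix(cells, nrow = vals["nrows"], ncol = vals["ncols"],
              byrow = TRUE)
  d[d == vals["nodata_value"]] <- NA_real_
  ascii_grid(d, xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
             cellsize = vals[["cellsize"]])
}

# Geometry shared by all grids of a panel: regular lattice covering the
# unique cell-centre coordinates.
.panel_geometry <- function(panel) {
  xs <- sort(unique(panel$x))
  ys <- sort(unique(panel$y))
  cs <- if (length(xs) > 1L) min(diff(xs)) else
    if (length(ys) > 1L) min(diff(ys)) else 1500
  x0 <- min(xs) - cs / 2
  y0 <- min(ys) - cs / 2
  ncols <- round((max(xs) + cs / 2 - x0) / cs)
  nrows <- round((max(ys) + cs / 2 - y0) / cs)
  list(xll = x0, yll = y0, cellsize = cs, ncols = ncols, nrows = nrows)
}

# One variable of a (single-year) panel slice onto the lattice.
.panel_to_grid <- function(sub, var, geo) {
  d <- matrix(NA_real_, nrow = geo$nrows, ncol = geo$ncols)
  col <- round((sub$x - geo$xll - geo$cellsize / 2) / geo$cellsize) + 1L
  row_from_bottom <- round((sub$y - geo$yll - geo$cellsize / 2) /
                             geo$cellsize) + 1L
  row <- geo$nrows - row_from_bottom + 1L  # row 1 = north
  idx <- cbind(row, col)
  if (anyDuplicated(idx)) stop("coordinate collisions while rasterizing")
  d[idx] <- sub[[var]]
  ascii_grid(d, xll = geo$xll, yll = geo$yll, cellsize = geo$cellsize)
}

#' Aggregate a grid to a coarser resolution
#'
#' Blocks of `factor` x `factor` fine cells, anchored at the grid's
#' upper-left corner, are reduced to one coarse cell each. Masked (`NA`)
#' cells are ignored by the reducer; partial windows at the right/bottom
#' edges are reduced over the available cells. An all-masked window
#' stays masked.
#'
#' @param grid An [ascii_grid()] or plain matrix.
#' @param factor Integer aggregation factor >= 1; 1 is the identity.
#' @param reducer Function applied to each window's unmasked cells
#'   (default `mean`, appropriate for weather and NPP rates).
#' @return Same class as `grid`, with dimensions `ceiling(fine/factor)`.
#' @export
#' @examples
#' g <- ascii_grid(matrix(1:4, 2, 2, byrow = TRUE))
#' aggregate_resolution(g, 2)$data  # single cell, mean 2.5
aggregate_resolution <- function(grid, factor, reducer = mean) {
  is_grid <- inherits(grid, "ascii_grid")
  d <- if (is_grid) grid$data else grid
  if (!is.matrix(d) || !length(d)) stop("empty grid")
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(grid)
  nr <- ceiling(nrow(d) / factor)
  nc <- ceiling(ncol(d) / factor)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- ((i - 1L) * factor + 1L):min(i * factor, nrow(d))
    for (j in seq_len(nc)) {
      ci <- ((j - 1L) * factor + 1L):min(j * factor, ncol(d))
      v <- d[ri, ci]
      v <- v[!is.na(v)]
      if (length(v)) out[i, j] <- reducer(v)
    }
  }
  if (is_grid)
    ascii_grid(out, xll = grid$xll,
               yll = grid$yll + (nrow(d) - nr * factor) * grid$cellsize,
               cellsize = grid$cellsize * factor)
  else out
}
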