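#' Construct a single-band raster grid layer
#'
#' A `grid_layer` is the atomic spatial input of the model: a numeric matrix
#' with square cells and a top-left georeference. Row 1 is the northern edge
#' and rows increase southward, matching the on-screen orientation of the
#' matrix. Cells marked with the layer's nodata value are stored as `NA`.
#'
#' @param values Numeric matrix (row 1 = north edge).
#' @param cell_size Cell edge length in metres; cells are square.
#' @param origin_x,origin_y Map coordinates of the *top-left corner* of the
#'   grid (metres). Defaults place the lower-left corner at (0, 0).
#' @param nodata Sentinel value used on disk for missing cells.
#' @return An object of class `grid_layer`.
#' @examples
#' g <- grid_layer(matrix(0, 3, 3), cell_size = 75)
#' g$n_rows
#' @export
grid_layer <- function(values, cell_size, origin_x = 0,
                       origin_y = nrow(values) * cell_size,
                       nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have at least one row and one column", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number", call. = FALSE)
  values[!is.na(values) & values == nodata] <- NA_real_
  structure(
    list(values = values, n_rows = nrow(values), n_cols = ncol(values),
         origin_x = as.double(origin_x), origin_y = as.double(origin_y),
         cell_size = as.double(cell_size), nodata = as.double(nodata)),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("<grid_layer> %d x %d cells of %g m, origin (%g, %g), nodata %g\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$nodata))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("  values in [%g, %g], %d NA cells\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.grid_layer <- function(x) c(x$n_rows, x$n_cols)

# two layers share the same lattice?
grids_aligned <- function(a, b, tol = 1e-6) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Map coordinates to grid cell indices
#'
#' Floor-based convention: a point on a shared cell edge belongs to the cell
#' with the larger index (the eastern / southern cell). Indices are 1-based
#' with row 1 at the north edge.
#'
#' @param layer A [grid_layer()] (or any object carrying `origin_x`,
#'   `origin_y`, `cell_size`).
#' @param x,y Numeric vectors of map coordinates.
#' @return A [tibble::tibble] with integer columns `row`, `col` and a logical
#'   `in_extent`.
#' @export
xy_to_cell <- function(layer, x, y) {
  col <- floor((x - layer$origin_x) / layer$cell_size) + 1
  row <- floor((layer$origin_y - y) / layer$cell_size) + 1
  tibble::tibble(
    row = as.integer(row), col = as.integer(col),
    in_extent = row >= 1 & row <= layer$n_rows & col >= 1 & col <= layer$n_cols
  )
}

#' Grid cell indices to map coordinates of cell centres
#'
#' @inheritParams xy_to_cell
#' @param row,col Integer vectors of 1-based cell indices.
#' @return A tibble with columns `x`, `y` (cell-centre coordinates, metres).
#' @export
cell_to_xy <- function(layer, row, col) {
  tibble::tibble(
    x = layer$origin_x + (col - 0.5) * layer$cell_size,
    y = layer$origin_y - (row - 0.5) * layer$cell_size
  )
}

#' Read a single-band raster grid
#'
#' Reads an ESRI ASCII grid (`.asc`), the plain-text raster interchange
#' format. Both `xllcorner`/`yllcorner` and `xllcenter`/`yllcenter` headers
#' are accepted; cells equal to the file's `NODATA_value` become `NA`.
#' GeoTIFF is recognised as a format name but not supported by this build.
#'
#' @param path Path to the raster file.
#' @param format `"esri_ascii"` (default) or `"geotiff"`.
#' @return A [grid_layer()].
#' @export
read_grid <- function(path, format = c("esri_ascii", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF input is not supported by this build; ",
         "convert to ESRI ASCII grid (e.g. gdal_translate -of AAIGrid)",
         call. = FALSE)
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2L && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2]); i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing georeferencing header in ", path, call. = FALSE)
  if (any(c("dx", "dy") %in% names(hdr)) && !isTRUE(hdr$dx == hdr$dy))
    stop("non-square cells are not supported", call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows); cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  if (is.null(xll) || is.null(yll))
    stop("missing georeferencing header in ", path, call. = FALSE)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " cell values, found ", length(vals),
         call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  grid_layer(m, cell_size = cs, origin_x = xll, origin_y = yll + nr * cs,
             nodata = nodata)
}

#' Write a grid layer as an ESRI ASCII raster
#'
#' Integer-valued grids round-trip bit-exactly; floating point values are
#' written with 17 significant digits. `NA` cells are written as the layer's
#' nodata value.
#'
#' @param layer A [grid_layer()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(layer, path) {
  v <- layer$values
  v[is.na(v)] <- layer$nodata
  intish <- all(v == round(v)) && max(abs(v)) < 2^53
  fmt <- function(x) {
    if (intish) sprintf("%.0f", x) else sprintf("%.17g", x)
  }
  hdr <- c(
    sprintf("ncols %d", layer$n_cols),
    sprintf("nrows %d", layer$n_rows),
    sprintf("xllcorner %.10f", layer$origin_x),
    sprintf("yllcorner %.10f", layer$origin_y - layer$n_rows * layer$cell_size),
    sprintf("cellsize %.10f", layer$cell_size),
    sprintf("NODATA_value %s", fmt(layer$nodata))
  )
  body <- apply(v, 1L, function(r) paste(fmt(r), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}
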