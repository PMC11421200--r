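#' Annual concentration grid
#'
#' A static annual-mean concentration raster on a regular lon/lat grid.
#' Cell (row r, col c), 1-based, covers the half-open box
#' `[origin_lon + (c-1)*s, origin_lon + c*s) x [origin_lat + (r-1)*s, origin_lat + r*s)`;
#' rows increase northward. Values are concentrations in ug/m^3; `NA` marks
#' nodata cells.
#'
#' @param values numeric matrix, `n_rows x n_cols`, row 1 = southernmost row.
#' @param origin_lon,origin_lat lower-left corner of cell (1,1), degrees.
#' @param cell_size cell edge in degrees (e.g. 0.01).
#' @return an object of class `annual_grid`.
#' @export
annual_grid <- function(values, origin_lon, origin_lat, cell_size) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), is.finite(origin_lon), is.finite(origin_lat))
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be > 0", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("annual grid contains negative concentrations", call. = FALSE)
  structure(
    list(values = values, origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size, n_rows = nrow(values), n_cols = ncol(values)),
    class = "annual_grid"
  )
}

#' @export
print.annual_grid <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf(
    "annual_grid: %d x %d cells of %g deg, origin (%g, %g)\n  values %.2f-%.2f ug/m^3, %d nodata cells\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat,
    rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' Locate grid cells containing points
#'
#' @param grid an [annual_grid()].
#' @param lon,lat coordinate vectors, degrees.
#' @return integer matrix with columns `row`, `col`; `NA` outside the grid.
#' @export
grid_cell <- function(grid, lon, lat) {
  # small forward nudge keeps exact decimal boundaries in the north-east cell
  # despite binary rounding of (x - origin) / cell_size
  col <- floor((lon - grid$origin_lon) / grid$cell_size + 1e-9) + 1
  row <- floor((lat - grid$origin_lat) / grid$cell_size + 1e-9) + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Sample the annual grid at points
#'
#' @inheritParams grid_cell
#' @param require_inside error (rather than return `NA`) for points outside
#'   the grid extent.
#' @return numeric vector of cell values, ug/m^3 (`NA` for nodata cells).
#' @export
grid_value <- function(grid, lon, lat, require_inside = TRUE) {
  rc <- grid_cell(grid, lon, lat)
  out <- rep(NA_real_, nrow(rc))
  inside <- !is.na(rc[, 1])
  if (require_inside && !all(inside)) {
    i <- which(!inside)[1]
    stop(sprintf("point (%g, %g) lies outside the annual grid", lon[i], lat[i]),
         call. = FALSE)
  }
  out[inside] <- grid$values[cbind(rc[inside, 1], rc[inside, 2])]
  out
}

# Cell-centre coordinates for (row, col) vectors.
grid_cell_center <- function(grid, row, col) {
  cbind(lon = grid$origin_lon + (col - 0.5) * grid$cell_size,
        lat = grid$origin_lat + (row - 0.5) * grid$cell_size)
}

#' Read an annual grid from an ESRI ASCII raster
#'
#' Parses the `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header
#' (case-insensitive; nodata optional) followed by `nrows` rows of values
#' from north to south. GeoTIFF input is detected and refused with a pointer
#' to `gdal_translate -of AAIGrid`; a projected CRS cannot be expressed in
#' this header so degree georeferencing is implied.
#'
#' @param path file path.
#' @return an [annual_grid()]; nodata cells are `NA`.
#' @export
read_annual_grid <- function(path) {
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) >= 4L &&
      (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
       identical(magic[1:2], as.raw(c(0x4d, 0x4d)))) &&
      magic[3] %in% as.raw(c(0x2a, 0x2b, 0x00)))
    stop("TIFF input is not supported; convert with gdal_translate -of AAIGrid",
         call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list(); i <- 1L
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(tok[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                    "nodata_value")) break
    v <- suppressWarnings(as.numeric(tok[2]))
    if (length(tok) != 2L || is.na(v))
      stop(sprintf("malformed ESRI ASCII header line: '%s'", lines[i]),
           call. = FALSE)
    hdr[[key]] <- v
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(sprintf("ESRI ASCII header missing: %s",
                 paste(setdiff(need, names(hdr)), collapse = ", ")),
         call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+"))))
  if (anyNA(vals) || length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("ESRI ASCII body: expected %d numeric values, found %d%s",
                 hdr$ncols * hdr$nrows, sum(!is.na(vals)),
                 if (anyNA(vals)) " (non-numeric tokens present)" else ""),
         call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # file is north-first
  annual_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' Write an annual grid (or density surface) as ESRI ASCII
#'
#' @param grid an [annual_grid()] or [kde_surface()] result.
#' @param path output path.
#' @param nodata numeric nodata marker used for `NA` cells.
#' @export
write_annual_grid <- function(grid, path, nodata = -9999) {
  m <- grid$values
  m[is.na(m)] <- nodata
  hdr <- sprintf(
    "ncols %d\nnrows %d\nxllcorner %.10g\nyllcorner %.10g\ncellsize %.10g\nNODATA_value %g",
    ncol(m), nrow(m), grid$origin_lon, grid$origin_lat, grid$cell_size, nodata)
  body <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1,
                function(r) paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
                                  collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
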