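# Minimal north-up lon/lat raster support (ESRI ASCII grid). Row 1 of the
# data matrix is the northern edge; registration is cell-center; the nodata
# mask is carried as NA.

#' Construct a grid layer
#'
#' @param data numeric matrix (rows x cols, row 1 = northern edge, `NA` =
#'   nodata).
#' @param xll,yll lower-left corner coordinates (degrees).
#' @param cellsize cell size in degrees.
#' @param nodata_value value used on disk for missing cells.
#' @return an object of class `grid_layer`.
#' @export
grid_layer <- function(data, xll = 0, yll = 0, cellsize = 1, nodata_value = -9999) {
  data <- as.matrix(data)
  structure(list(data = data, xll = xll, yll = yll,
                 cellsize = cellsize, nodata_value = nodata_value),
            class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("grid_layer: %d x %d cells, cellsize %g deg, origin (%g, %g), %d nodata\n",
              nrow(x$data), ncol(x$data), x$cellsize, x$xll, x$yll,
              sum(is.na(x$data))))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return a [grid_layer()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]])) stopf("missing header field %s in %s", key, path)
  }
  if (is.null(hdr$xllcorner) || is.null(hdr$yllcorner)) {
    # cell-center registration variant
    if (!is.null(hdr$xllcenter) && !is.null(hdr$yllcenter)) {
      hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
      hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
    } else stopf("missing xllcorner/yllcorner in %s", path)
  }
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stopf("grid body has %d values but header promises %d x %d",
          length(vals), hdr$nrows, hdr$ncols)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  grid_layer(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
             cellsize = hdr$cellsize, nodata_value = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param layer a [grid_layer()] or plain matrix.
#' @param path output path.
#' @param digits significant digits written (default 10; round-trips
#'   typical climate values exactly at the stated precision).
#' @inheritParams grid_layer
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path, digits = 10,
                             xll = 0, yll = 0, cellsize = 1, nodata_value = -9999) {
  if (!inherits(layer, "grid_layer")) {
    layer <- grid_layer(layer, xll, yll, cellsize, nodata_value)
  }
  m <- layer$data
  m[is.na(m)] <- layer$nodata_value
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.15g", layer$xll),
           sprintf("yllcorner %.15g", layer$yll),
           sprintf("cellsize %.15g", layer$cellsize),
           sprintf("NODATA_value %g", layer$nodata_value))
  body <- apply(m, 1, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Multi-variable climate stack at one time
#'
#' @param variables named list of numeric matrices sharing one grid and
#'   nodata mask.
#' @param grid list with `nrows`, `ncols`, `xll`, `yll`, `cellsize`.
#' @param time time of the stack in ky BP.
#' @return an object of class `climate_stack`.
#' @export
climate_stack <- function(variables, grid, time = 0) {
  stopifnot(is.list(variables), length(variables) >= 1)
  dims <- vapply(variables, dim, integer(2))
  if (any(dims[1, ] != grid$nrows) || any(dims[2, ] != grid$ncols)) {
    stopf("all layers must match the %d x %d grid", grid$nrows, grid$ncols)
  }
  masks <- vapply(variables, function(m) sum(is.na(m)), integer(1))
  if (length(unique(masks)) > 1 ||
      (masks[1] > 0 && !all(vapply(variables[-1], function(m)
        identical(is.na(m), is.na(variables[[1]])), logical(1))))) {
    stopf("all layers must share one nodata mask")
  }
  structure(list(variables = variables, grid = grid, time = time),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack @ %g ky BP: %d variables on %d x %d grid\n",
              x$time, length(x$variables), x$grid$nrows, x$grid$ncols))
  invisible(x)
}

# flatten a stack to a cells x variables matrix (masked cells dropped)
stack_matrix <- function(stack, keep_mask = FALSE) {
  mats <- stack$variables
  mask <- !is.na(mats[[1]])
  m <- vapply(mats, function(x) x[mask], numeric(sum(mask)))
  colnames(m) <- names(mats)
  if (keep_mask) list(values = m, mask = mask) else m
}

# lon/lat of every cell center, matching stack_matrix() ordering
cell_centers <- function(grid, mask = NULL) {
  ri <- matrix(seq_len(grid$nrows), grid$nrows, grid$ncols)
  cj <- matrix(rep(seq_len(grid$ncols), each = grid$nrows), grid$nrows, grid$ncols)
  lon <- grid$xll + (cj - 0.5) * grid$cellsize
  lat <- grid$yll + (grid$nrows - ri + 0.5) * grid$cellsize
  if (is.null(mask)) mask <- matrix(TRUE, grid$nrows, grid$ncols)
  cbind(lon = lon[mask], lat = lat[mask])
}

# row/col of grid cells containing lon/lat points
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$xll) / grid$cellsize) + 1
  row <- grid$nrows - floor((lat - grid$yll) / grid$cellsize)
  bad <- col < 1 | col > grid$ncols | row < 1 | row > grid$nrows
  if (any(bad)) stopf("%d point(s) fall outside the grid", sum(bad))
  cbind(row = as.integer(row), col = as.integer(col))
}
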