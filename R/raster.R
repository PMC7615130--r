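#' Raster grids
#'
#' A `raster_grid` holds a numeric value matrix (rows from the top of the
#' map down, matching the on-disk ESRI ASCII convention), a lower-left
#' corner, a square cell size in metres, a nodata sentinel, and a CRS label.
#' Cell (r, c) has its centre at
#' `x = xll + (c - 1/2) * cellsize`, `y = yll + (nrow - r + 1/2) * cellsize`;
#' the affine pixel-to-coordinate map is bijective by construction.
#'
#' @param values numeric matrix (row 1 = northernmost row)
#' @param xll,yll planar coordinates of the lower-left corner (metres)
#' @param cellsize cell edge length (metres)
#' @param nodata sentinel for missing cells
#' @param crs CRS label (planar metres assumed)
#' @return object of class `raster_grid`
#' @export
raster_grid <- function(values, xll, yll, cellsize, nodata = -9999,
                        crs = "LOCAL-TM (metres)") {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata, crs = crs),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat("<raster_grid> ", nrow(x$values), "x", ncol(x$values),
      " cells @ ", x$cellsize, " m, origin (", x$xll, ", ", x$yll,
      "), CRS: ", x$crs, "\n", sep = "")
  invisible(x)
}

raster_bbox <- function(r) {
  c(r$xll, r$yll,
    r$xll + ncol(r$values) * r$cellsize,
    r$yll + nrow(r$values) * r$cellsize)
}

# matrix of finite values with nodata replaced by NA
raster_values_na <- function(r) {
  v <- r$values
  v[v == r$nodata] <- NA_real_
  v
}

cell_centre_x <- function(r, col) r$xll + (col - 0.5) * r$cellsize
cell_centre_y <- function(r, row) r$yll + (nrow(r$values) - row + 0.5) * r$cellsize

# column/row index of the cell containing a point (clamped to the grid)
cell_index <- function(r, x, y) {
  col <- pmin(pmax(ceiling((x - r$xll) / r$cellsize), 1L), ncol(r$values))
  row <- pmin(pmax(nrow(r$values) - ceiling((y - r$yll) / r$cellsize) + 1L, 1L),
              nrow(r$values))
  cbind(row, col)
}

#' Write a raster to an ESRI ASCII grid (.asc) file
#' @param r a [raster_grid()]
#' @param path output path
#' @export
write_asc <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(r$values)),
    paste("nrows", nrow(r$values)),
    paste("xllcorner", format(r$xll, scientific = FALSE)),
    paste("yllcorner", format(r$yll, scientific = FALSE)),
    paste("cellsize", format(r$cellsize, scientific = FALSE)),
    paste("NODATA_value", r$nodata)
  ), con)
  apply(r$values, 1, function(row) {
    writeLines(paste(format(row, trim = TRUE, digits = 10), collapse = " "),
               con)
  })
  invisible(path)
}

#' Read an ESRI ASCII grid (.asc) file
#' @param path input path
#' @param crs CRS label to attach
#' @return a [raster_grid()]
#' @export
read_asc <- function(path, crs = "LOCAL-TM (metres)") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  stopifnot(nrow(vals) == hdr$nrows, ncol(vals) == hdr$ncols)
  raster_grid(vals, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
              nodata = hdr$nodata_value %||% -9999, crs = crs)
}

rasters_aligned <- function(a, b) {
  isTRUE(all.equal(c(a$xll, a$yll, a$cellsize, dim(a$values)),
                   c(b$xll, b$yll, b$cellsize, dim(b$values))))
}

#' Normalized difference vegetation index from red and NIR bands
#'
#' `(NIR - red) / (NIR + red)` per cell. Cells where the denominator is zero
#' (or either band is nodata) become nodata. Outputs lie in `[-1, 1]` for
#' non-negative reflectances.
#'
#' @param red,nir aligned [raster_grid()] bands
#' @return a [raster_grid()] of NDVI values
#' @export
ndvi <- function(red, nir) {
  if (!rasters_aligned(red, nir)) {
    stop("ndvi: red and NIR grids are not aligned ",
         "(origin, cell size and dimensions must match)")
  }
  rv <- raster_values_na(red)
  nv <- raster_values_na(nir)
  den <- nv + rv
  out <- (nv - rv) / den
  out[!is.finite(out) | den == 0] <- NA_real_
  out[is.na(out)] <- -9999
  raster_grid(out, red$xll, red$yll, red$cellsize, nodata = -9999,
              crs = red$crs)
}

# cells of r whose centres fall inside polygon g; returns values (NA for
# nodata) — empty when no centre is inside
cells_in_polygon <- function(r, g) {
  bb <- ring_bbox(g)
  idx <- cell_range(r, bb)
  if (is.null(idx)) return(numeric(0))
  cc <- expand_centres(r, idx)
  inside <- cpp_points_in_poly(cc$x, cc$y, g[, 1], g[, 2])
  if (!any(inside)) return(numeric(0))
  vals <- r$values[cbind(cc$row[inside], cc$col[inside])]
  vals[vals == r$nodata] <- NA_real_
  vals
}

# row/col ranges of cells whose centres could fall in bbox (plus margin)
cell_range <- function(r, bb, margin = 0) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  c0 <- floor((bb[1] - margin - r$xll) / r$cellsize - 0.5) + 1
  c1 <- ceiling((bb[3] + margin - r$xll) / r$cellsize + 0.5)
  top <- r$yll + nr * r$cellsize
  r0 <- floor((top - (bb[4] + margin)) / r$cellsize - 0.5) + 1
  r1 <- ceiling((top - (bb[2] - margin)) / r$cellsize + 0.5)
  c0 <- max(1, c0); c1 <- min(nc, c1); r0 <- max(1, r0); r1 <- min(nr, r1)
  if (c0 > c1 || r0 > r1) return(NULL)
  list(rows = r0:r1, cols = c0:c1)
}

expand_centres <- function(r, idx) {
  rows <- rep(idx$rows, times = length(idx$cols))
  cols <- rep(idx$cols, each = length(idx$rows))
  list(row = rows, col = cols,
       x = cell_centre_x(r, cols), y = cell_centre_y(r, rows))
}

#' Zonal mean of a raster over EA polygons
#'
#' The mean of all cells whose centres fall inside each polygon, ignoring
#' nodata. Polygons smaller than one cell (no centre inside) fall back to
#' the value of the cell containing the polygon centroid.
#'
#' @param r a [raster_grid()]
#' @param frame an [ea_frame()]
#' @return numeric vector, one mean per EA (frame row order)
#' @export
zonal_mean <- function(r, frame) {
  rb <- raster_bbox(r)
  vapply(seq_len(nrow(frame)), function(i) {
    g <- frame$geometry[[i]]
    bb <- ring_bbox(g)
    if (bb[1] >= rb[3] || bb[3] <= rb[1] || bb[2] >= rb[4] || bb[4] <= rb[2]) {
      stop("zonal_mean: polygon for EA '", frame$ea_id[i],
           "' lies entirely outside the raster extent")
    }
    vals <- cells_in_polygon(r, g)
    vals <- vals[!is.na(vals)]
    if (length(vals)) return(mean(vals))
    ct <- ring_centroid(g)
    rc <- cell_index(r, ct[1], ct[2])
    v <- r$values[rc]
    if (v == r$nodata) NA_real_ else v
  }, 0)
}

#' Elevation of each EA relative to its surroundings
#'
#' Zonal mean of the DEM over the EA polygon minus the zonal mean over the
#' surrounding annulus: all cells whose centres lie within `buffer_km` of
#' the polygon but outside it (set `include_self = TRUE` to include the EA
#' itself in the buffer mean). Used as a flood-risk proxy: negative values
#' flag EAs lying below their surroundings.
#'
#' @param dem a [raster_grid()] of elevations (metres)
#' @param frame an [ea_frame()]
#' @param buffer_km buffer radius in kilometres (default 5)
#' @param include_self include the EA's own cells in the buffer mean
#' @return numeric vector of elevation differences (metres)
#' @export
elevation_diff <- function(dem, frame, buffer_km = 5, include_self = FALSE) {
  buf <- buffer_km * 1000
  rb <- raster_bbox(dem)
  vapply(seq_len(nrow(frame)), function(i) {
    g <- frame$geometry[[i]]
    bb <- ring_bbox(g)
    if (bb[1] - buf < rb[1] - dem$cellsize ||
        bb[2] - buf < rb[2] - dem$cellsize ||
        bb[3] + buf > rb[3] + dem$cellsize ||
        bb[4] + buf > rb[4] + dem$cellsize) {
      stop("elevation_diff: raster does not cover the ", buffer_km,
           "-km buffer of EA '", frame$ea_id[i], "'")
    }
    idx <- cell_range(dem, bb, margin = buf)
    cc <- expand_centres(dem, idx)
    inside <- cpp_points_in_poly(cc$x, cc$y, g[, 1], g[, 2])
    dist <- cpp_dist_to_boundary(cc$x, cc$y, g[, 1], g[, 2])
    vals <- dem$values[cbind(cc$row, cc$col)]
    vals[vals == dem$nodata] <- NA_real_
    ea_vals <- vals[inside]
    ea_mean <- if (any(!is.na(ea_vals))) mean(ea_vals, na.rm = TRUE) else {
      ct <- ring_centroid(g)
      rc <- cell_index(dem, ct[1], ct[2])
      v <- dem$values[rc]
      if (v == dem$nodata) NA_real_ else v
    }
    ann <- !inside & dist <= buf
    if (include_self) ann <- ann | inside
    ann_mean <- mean(vals[ann], na.rm = TRUE)
    ea_mean - ann_mean
  }, 0)
}
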