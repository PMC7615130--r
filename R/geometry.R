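#' EA frames: planar polygon tables
#'
#' An `ea_frame` is a `data.frame` with one row per enumeration area (EA):
#' `ea_id`, `neighbourhood`, `population`, `urban`, optional `deprived`
#' label, and a `geometry` list-column of closed polygon rings (n x 2
#' coordinate matrices in a planar coordinate system, metres). The CRS label
#' is kept as an attribute; all internal computation assumes planar metres.
#'
#' @param df data.frame with at least `ea_id`, `neighbourhood`, `population`,
#'   `urban` columns.
#' @param geometry list of n x 2 numeric matrices (polygon exterior rings,
#'   not necessarily closed; rings are stored unclosed).
#' @param crs CRS label; any label not matching a geographic (degree) CRS is
#'   treated as planar metres.
#' @return an object of class `ea_frame`.
#' @export
ea_frame <- function(df, geometry, crs = "LOCAL-TM (metres)") {
  stopifnot(is.data.frame(df), is.list(geometry),
            nrow(df) == length(geometry))
  need <- c("ea_id", "neighbourhood", "population", "urban")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ea_frame: missing columns: ",
                         paste(miss, collapse = ", "))
  geometry <- lapply(geometry, function(g) {
    g <- as.matrix(g)
    if (ncol(g) != 2 || nrow(g) < 3) stop("ea_frame: invalid polygon ring")
    # drop a duplicated closing vertex
    if (all(g[1, ] == g[nrow(g), ])) g <- g[-nrow(g), , drop = FALSE]
    if (abs(ring_area(g)) <= 0) stop("ea_frame: zero-area polygon")
    unname(g)
  })
  df$geometry <- I(geometry)
  attr(df, "crs") <- crs
  class(df) <- c("ea_frame", class(df))
  df
}

#' @export
print.ea_frame <- function(x, ...) {
  cat("<ea_frame> ", nrow(x), " EAs, ",
      length(unique(x$neighbourhood)), " neighbourhoods, CRS: ",
      attr(x, "crs"), "\n", sep = "")
  print(head(as.data.frame(x)[setdiff(names(x), "geometry")]), ...)
  invisible(x)
}

crs_is_planar <- function(frame) {
  !grepl("4326|WGS ?84|longlat|degree", attr(frame, "crs") %||% "",
         ignore.case = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# signed shoelace area (m^2); positive for counter-clockwise rings
ring_area <- function(g) {
  x <- g[, 1]; y <- g[, 2]
  j <- c(nrow(g), seq_len(nrow(g) - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Polygon areas of an EA frame in square kilometres
#' @param frame an [ea_frame()]
#' @return numeric vector of areas (km^2)
#' @export
ea_areas_km2 <- function(frame) {
  vapply(frame$geometry, function(g) abs(ring_area(g)), 0) / 1e6
}

ring_centroid <- function(g) {
  x <- g[, 1]; y <- g[, 2]
  j <- c(nrow(g), seq_len(nrow(g) - 1))
  a <- ring_area(g)
  w <- x[j] * y - x * y[j]
  c(sum((x[j] + x) * w) / (6 * a), sum((y[j] + y) * w) / (6 * a))
}

ring_bbox <- function(g) c(min(g[, 1]), min(g[, 2]), max(g[, 1]), max(g[, 2]))

frame_bbox <- function(frame) {
  bb <- vapply(frame$geometry, ring_bbox, numeric(4))
  c(min(bb[1, ]), min(bb[2, ]), max(bb[3, ]), max(bb[4, ]))
}

#' EA centroids
#' @param frame an [ea_frame()]
#' @return n x 2 matrix of centroid coordinates (metres)
#' @export
ea_centroids <- function(frame) {
  t(vapply(frame$geometry, ring_centroid, numeric(2)))
}

# queen adjacency: polygons are neighbours iff their boundaries come within
# `tol` metres (shared vertex or edge => gap 0). Returns a list of integer
# neighbour vectors. Bounding boxes prune the O(n^2) candidate set.
queen_adjacency <- function(frame, tol = 1e-6) {
  n <- nrow(frame)
  bb <- t(vapply(frame$geometry, ring_bbox, numeric(4)))
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  ord <- order(bb[, 1])
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (bb[j, 1] > bb[i, 3] + tol) break
      if (bb[j, 2] > bb[i, 4] + tol || bb[j, 4] < bb[i, 2] - tol) next
      gi <- frame$geometry[[i]]; gj <- frame$geometry[[j]]
      if (cpp_poly_gap(gi[, 1], gi[, 2], gj[, 1], gj[, 2]) <= tol) {
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  lapply(nb, sort)
}

#' Write an EA frame (plus any extra attribute columns) to GeoJSON
#'
#' Coordinates are written in the frame's planar CRS; the CRS label is
#' stored in a `crs_label` member so round-trips preserve it.
#'
#' @param frame an [ea_frame()]
#' @param path output file
#' @export
write_ea_geojson <- function(frame, path) {
  props <- as.data.frame(frame)[setdiff(names(frame), "geometry")]
  feats <- lapply(seq_len(nrow(frame)), function(i) {
    g <- frame$geometry[[i]]
    ring <- rbind(g, g[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = as.list(props[i, , drop = FALSE]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(r) ring[r, ])))
    )
  })
  obj <- list(type = "FeatureCollection",
              crs_label = attr(frame, "crs"),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EA frame from GeoJSON written by [write_ea_geojson()]
#' @param path GeoJSON file
#' @return an [ea_frame()]
#' @export
read_ea_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  feats <- obj$features
  geometry <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    m
  })
  props <- do.call(rbind, lapply(feats, function(f) {
    as.data.frame(lapply(f$properties, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  }))
  ea_frame(props, geometry, crs = obj$crs_label %||% "LOCAL-TM (metres)")
}
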