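#' Simple polygon geometry
#'
#' Polygons live in the grid's abstract map units. A polygon is a list of
#' rings (closed, 2-column coordinate matrices); the first ring is the
#' exterior, later rings punch holes (even-odd rule). This is all the
#' vector machinery the pipeline needs: reserve footprints are either
#' supplied polygons or area-preserving circular buffers.
#'
#' @param ... one or more 2-column numeric matrices (x, y), each a ring
#'   with at least 3 distinct vertices. Call with no arguments for the
#'   empty polygon.
#' @return An object of class `sc_polygon`.
#' @export
sc_polygon <- function(...) {
  rings <- list(...)
  if (length(rings) == 1L && is.list(rings[[1L]]) && !is.matrix(rings[[1L]]))
    rings <- rings[[1L]]
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L || nrow(r) < 3L)
      stop("each ring needs a 2-column matrix with >= 3 vertices")
    if (!all(is.finite(r))) stop("ring coordinates must be finite")
    # drop a repeated closing vertex; rings are implicitly closed
    if (nrow(r) > 3L && all(r[1L, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    r
  })
  structure(list(rings = rings), class = "sc_polygon")
}

#' @export
print.sc_polygon <- function(x, ...) {
  if (!length(x$rings)) cat("sc_polygon: EMPTY\n")
  else cat(sprintf("sc_polygon: %d ring(s), %d vertices, area %g\n",
                   length(x$rings), sum(vapply(x$rings, nrow, 1L)),
                   polygon_area(x)))
  invisible(x)
}

is_empty_polygon <- function(poly) length(poly$rings) == 0L

#' Signed shoelace area of one ring
#' @noRd
ring_area <- function(r) {
  n <- nrow(r)
  j <- c(2:n, 1L)
  abs(sum(r[, 1L] * r[j, 2L] - r[j, 1L] * r[, 2L])) / 2
}

#' Planar area of a polygon (exterior minus holes)
#' @param poly an [sc_polygon].
#' @return area in squared map units.
#' @export
polygon_area <- function(poly) {
  stopifnot(inherits(poly, "sc_polygon"))
  if (is_empty_polygon(poly)) return(0)
  a <- vapply(poly$rings, ring_area, 0)
  a[1L] - sum(a[-1L])
}

# segment intersection test for validity checking (proper crossings only)
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

ring_self_intersects <- function(r) {
  n <- nrow(r)
  if (n < 4L) return(FALSE)
  idx <- cbind(seq_len(n), c(2:n, 1L))
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (segments_cross(r[idx[i, 1L], ], r[idx[i, 2L], ],
                         r[idx[j, 1L], ], r[idx[j, 2L], ])) return(TRUE)
    }
  }
  FALSE
}

#' Check polygon validity
#' @param poly an [sc_polygon].
#' @return TRUE, or stops with a diagnostic naming the offending ring.
#' @export
validate_polygon <- function(poly) {
  stopifnot(inherits(poly, "sc_polygon"))
  for (i in seq_along(poly$rings)) {
    if (ring_self_intersects(poly$rings[[i]]))
      stop(sprintf("invalid geometry: ring %d is self-intersecting", i))
    if (ring_area(poly$rings[[i]]) <= 0)
      stop(sprintf("invalid geometry: ring %d has zero area", i))
  }
  TRUE
}

#' Rasterize a polygon onto a grid
#'
#' Cell membership is by cell center: a cell is true iff its center lies
#' inside the polygon under the even-odd rule (holes subtract). This
#' matches binary-mask semantics and is unbiased at fine resolution.
#' When `terrestrial = TRUE` the result is intersected with the land
#' mask.
#'
#' @param poly an [sc_polygon] in map units.
#' @param grid a [grid_spec].
#' @param name label for the layer.
#' @param terrestrial intersect with land (default TRUE).
#' @return A `binary_layer`.
#' @examples
#' g <- grid_spec(8, 8)
#' sq <- sc_polygon(cbind(c(2, 5, 5, 2), c(2, 2, 5, 5)))
#' mask_area(rasterize_polygon(sq, g))  # 9 unit cells
#' @export
rasterize_polygon <- function(poly, grid, name = "polygon",
                              terrestrial = TRUE) {
  stopifnot(inherits(poly, "sc_polygon"), inherits(grid, "grid_spec"))
  v <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (!is_empty_polygon(poly)) {
    validate_polygon(poly)
    cc <- cell_centers(grid)
    bb <- do.call(rbind, poly$rings)
    cols <- which(cc$x >= min(bb[, 1L]) & cc$x <= max(bb[, 1L]))
    rows <- which(cc$y >= min(bb[, 2L]) & cc$y <= max(bb[, 2L]))
    if (length(cols) && length(rows)) {
      px <- rep(cc$x[cols], each = length(rows))
      py <- rep(cc$y[rows], times = length(cols))
      inside <- rep(FALSE, length(px))
      for (r in poly$rings)  # even-odd: each containing ring flips parity
        inside <- xor(inside,
                      pracma::inpolygon(px, py, r[, 1L], r[, 2L]))
      v[cbind(rep(rows, times = length(cols)),
              rep(cols, each = length(rows)))] <- inside
    }
  }
  binary_layer(grid, v, name = name, terrestrial = terrestrial)
}

#' Regular-polygon disc with exact target area
#'
#' Approximates a disc by a regular `n`-gon whose circumradius is
#' inflated so the polygon area equals the requested disc area exactly
#' (a raw n-gon inscribed in the circle under-covers by a factor
#' `n sin(2*pi/n) / (2*pi)`).
#'
#' @param center numeric length-2 (x, y).
#' @param area target planar area (> 0).
#' @param n number of vertices (default 64).
#' @return An [sc_polygon].
#' @export
disc_polygon <- function(center, area, n = 64L) {
  stopifnot(length(center) == 2L, area > 0, n >= 8L)
  r_circle <- sqrt(area / pi)
  r <- r_circle * sqrt(2 * pi / (n * sin(2 * pi / n)))
  th <- 2 * pi * (seq_len(n) - 1L) / n
  sc_polygon(cbind(center[1L] + r * cos(th), center[2L] + r * sin(th)))
}

## ---- WKT ----

#' Serialize a polygon to WKT
#' @param poly an [sc_polygon].
#' @return a `POLYGON (...)` or `POLYGON EMPTY` string.
#' @export
polygon_to_wkt <- function(poly) {
  stopifnot(inherits(poly, "sc_polygon"))
  if (is_empty_polygon(poly)) return("POLYGON EMPTY")
  rings <- vapply(poly$rings, function(r) {
    r <- rbind(r, r[1L, ])  # WKT rings are explicitly closed
    paste0("(", paste(sprintf("%.10g %.10g", r[, 1L], r[, 2L]),
                      collapse = ", "), ")")
  }, "")
  paste0("POLYGON (", paste(rings, collapse = ", "), ")")
}

#' Parse a WKT POLYGON
#' @param wkt a `POLYGON (...)` string (holes supported); `POLYGON EMPTY`
#'   yields the empty polygon.
#' @return An [sc_polygon].
#' @export
wkt_to_polygon <- function(wkt) {
  wkt <- trimws(wkt)
  if (toupper(wkt) == "POLYGON EMPTY" || wkt == "") return(sc_polygon())
  if (!grepl("^POLYGON\\s*\\(", wkt, ignore.case = TRUE))
    stop("only POLYGON WKT is supported, got: ", substr(wkt, 1, 30))
  body <- sub("^POLYGON\\s*\\(", "", wkt, ignore.case = TRUE)
  body <- sub("\\)\\s*$", "", body)
  rings <- regmatches(body, gregexpr("\\(([^()]*)\\)", body))[[1L]]
  rings <- lapply(rings, function(s) {
    s <- gsub("[()]", "", s)
    pts <- strsplit(trimws(strsplit(s, ",")[[1L]]), "\\s+")
    m <- do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
    if (anyNA(m)) stop("malformed WKT coordinates")
    m
  })
  sc_polygon(rings)
}

## ---- GeoJSON ----

#' Write reserve geometries as a GeoJSON FeatureCollection
#' @param records list of `reserve_record` objects (see [load_reserves]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
reserves_to_geojson <- function(records, path) {
  feats <- lapply(records, function(rec) {
    geom <- if (!is.null(rec$geometry) && !is_empty_polygon(rec$geometry)) {
      list(type = "Polygon",
           coordinates = lapply(rec$geometry$rings, function(r) {
             r <- rbind(r, r[1L, ])
             lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L]))
           }))
    } else {
      list(type = "Point", coordinates = c(rec$centroid[1L], rec$centroid[2L]))
    }
    list(type = "Feature",
         properties = list(id = rec$id, network = rec$network,
                           area_km2 = rec$terrestrial_area,
                           year = rec$designation_year,
                           region = rec$region, country = rec$country,
                           status = rec$status, desig = rec$desig_label),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
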