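#' Abstract equal-area grid specification
#'
#' A `grid_spec` is the raster frame every layer in a run shares: a
#' `n_rows` x `n_cols` matrix of cells in abstract map units, with a
#' per-cell area weight in km2 and a terrestrial (land) mask. The grid is
#' equal-area by default (`cell_area` scalar); a full matrix of weights
#' supports latitude-varying cells. Indexing is row-major with row 1 at
#' the top; map coordinates put the origin at the grid's lower-left
#' corner, so cell (r, c) has its center at
#' `x = (c - 0.5) * cell_size`, `y = (n_rows - r + 0.5) * cell_size`.
#'
#' @param n_rows,n_cols positive integers, grid shape.
#' @param cell_size cell edge length in map units (default 1).
#' @param cell_area per-cell area weight in km2: a positive scalar or an
#'   `n_rows` x `n_cols` matrix of positive weights.
#' @param land logical matrix of terrestrial cells, or `NULL` for
#'   all-land.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(10, 10)
#' mask_area(land_mask(g))  # 100 km2
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 1, cell_area = 1,
                      land = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  if (is.matrix(cell_area)) {
    if (!all(dim(cell_area) == c(n_rows, n_cols)))
      stop("cell_area matrix must be n_rows x n_cols")
    if (!all(cell_area > 0)) stop("all cell_area weights must be > 0")
  } else {
    if (length(cell_area) != 1L || cell_area <= 0)
      stop("scalar cell_area must be a single positive number")
  }
  if (is.null(land)) {
    land <- matrix(TRUE, n_rows, n_cols)
  } else {
    if (!is.logical(land) || !all(dim(land) == c(n_rows, n_cols)))
      stop("land must be a logical n_rows x n_cols matrix")
    land[is.na(land)] <- FALSE
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = cell_size, cell_area = cell_area, land = land),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells (size %g), land %d/%d, area %g km2\n",
              x$n_rows, x$n_cols, x$cell_size, sum(x$land),
              x$n_rows * x$n_cols, sum(cell_areas(x)[x$land])))
  invisible(x)
}

#' Per-cell area weights as a full matrix
#' @param grid a [grid_spec].
#' @return numeric `n_rows` x `n_cols` matrix of km2 weights.
#' @export
cell_areas <- function(grid) {
  if (is.matrix(grid$cell_area)) grid$cell_area
  else matrix(grid$cell_area, grid$n_rows, grid$n_cols)
}

#' Coordinates of cell centers
#' @param grid a [grid_spec].
#' @return list with vectors `x` (length `n_cols`) and `y` (length
#'   `n_rows`, top row first).
#' @export
cell_centers <- function(grid) {
  list(x = (seq_len(grid$n_cols) - 0.5) * grid$cell_size,
       y = (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$cell_size)
}

same_grid <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$cell_area, b$cell_area)) &&
    identical(a$land, b$land)
}

#' Boolean per-cell mask layer
#'
#' Binary layers carry template masks, reserve-network footprints and the
#' land mask itself. A layer declared `terrestrial` is intersected with
#' the grid's land mask on construction, so no terrestrial layer is ever
#' true over ocean.
#'
#' @param grid a [grid_spec].
#' @param values logical matrix matching the grid shape (NA treated as
#'   FALSE).
#' @param name label recording provenance.
#' @param terrestrial intersect with the land mask (default TRUE).
#' @return An object of class `binary_layer`.
#' @export
binary_layer <- function(grid, values, name = "mask", terrestrial = TRUE) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(values) || !all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("values must be a matrix matching the grid shape")
  values <- values & TRUE          # coerce to logical
  values[is.na(values)] <- FALSE
  if (terrestrial) values <- values & grid$land
  structure(list(grid = grid, values = values, name = name,
                 terrestrial = terrestrial),
            class = "binary_layer")
}

#' The grid's land mask as a binary layer
#' @param grid a [grid_spec].
#' @return A `binary_layer` named "land".
#' @export
land_mask <- function(grid) binary_layer(grid, grid$land, name = "land")

#' @export
print.binary_layer <- function(x, ...) {
  cat(sprintf("binary_layer '%s': %d true / %d cells, area %g km2\n",
              x$name, sum(x$values), length(x$values), mask_area(x)))
  invisible(x)
}

#' Continuous per-cell layer
#'
#' Carries habitat quality, CVI and pressure surfaces. Missing cells are
#' `NA`; cells outside the land mask are forced missing.
#'
#' @param grid a [grid_spec].
#' @param values numeric matrix matching the grid shape; `NA` marks
#'   missing.
#' @param name label.
#' @return An object of class `continuous_layer`.
#' @export
continuous_layer <- function(grid, values, name = "layer") {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(values) || !all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("values must be a matrix matching the grid shape")
  values[!grid$land] <- NA_real_
  if (any(is.infinite(values), na.rm = TRUE))
    stop("continuous layer values must be finite where not missing")
  structure(list(grid = grid, values = values, name = name),
            class = "continuous_layer")
}

#' @export
print.continuous_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("continuous_layer '%s': %d valid cells, range [%g, %g]\n",
              x$name, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Zone partition of the land
#'
#' Assigns every land cell to exactly one zone (province, region, country
#' or biome). Zones drive stratified coverage, zonal means and the
#' province-level prioritization.
#'
#' @param grid a [grid_spec].
#' @param zone_id integer matrix matching the grid shape; `NA` outside
#'   land.
#' @param zone_table data.frame with columns `zone_id` and `name`; built
#'   from the ids present if omitted.
#' @return An object of class `zone_partition`.
#' @export
zone_partition <- function(grid, zone_id, zone_table = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(zone_id) || !all(dim(zone_id) == c(grid$n_rows, grid$n_cols)))
    stop("zone_id must be a matrix matching the grid shape")
  mode(zone_id) <- "integer"
  zone_id[!grid$land] <- NA_integer_
  if (anyNA(zone_id[grid$land]))
    stop("every land cell must carry a zone id")
  ids <- sort(unique(as.vector(zone_id[grid$land])))
  if (is.null(zone_table)) {
    zone_table <- data.frame(zone_id = ids, name = paste0("zone_", ids),
                             stringsAsFactors = FALSE)
  } else {
    if (!all(c("zone_id", "name") %in% names(zone_table)))
      stop("zone_table needs columns 'zone_id' and 'name'")
    if (!all(ids %in% zone_table$zone_id))
      stop("zone ids present on the grid are missing from zone_table: ",
           paste(setdiff(ids, zone_table$zone_id), collapse = ", "))
  }
  structure(list(grid = grid, zone_id = zone_id, zone_table = zone_table),
            class = "zone_partition")
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf("zone_partition: %d zones over %d land cells\n",
              nrow(x$zone_table), sum(x$grid$land)))
  invisible(x)
}

#' Union of binary masks
#'
#' Cell-wise OR over any number of layers on one grid; this is how
#' reserve networks are merged and how biosphere reserves are overlaid on
#' the protected-area network. Overlaps are counted once by construction.
#'
#' @param ... `binary_layer` objects, or a single list of them.
#' @param name label for the result; derived from inputs if `NULL`.
#' @return A `binary_layer`.
#' @export
union_masks <- function(..., name = NULL) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1L]], "binary_layer"))
    layers <- layers[[1L]]
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "binary_layer")))
  g <- layers[[1L]]$grid
  for (l in layers[-1L])
    if (!same_grid(g, l$grid)) stop("union_masks: layers on different grids")
  v <- Reduce(`|`, lapply(layers, `[[`, "values"))
  if (is.null(name))
    name <- paste(vapply(layers, `[[`, "", "name"), collapse = " | ")
  binary_layer(g, v, name = name,
               terrestrial = all(vapply(layers, `[[`, TRUE, "terrestrial")))
}

#' Intersection of binary masks
#' @inheritParams union_masks
#' @return A `binary_layer` true where every input is true.
#' @export
intersect_masks <- function(..., name = NULL) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1L]], "binary_layer"))
    layers <- layers[[1L]]
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "binary_layer")))
  g <- layers[[1L]]$grid
  for (l in layers[-1L])
    if (!same_grid(g, l$grid)) stop("intersect_masks: layers on different grids")
  v <- Reduce(`&`, lapply(layers, `[[`, "values"))
  if (is.null(name))
    name <- paste(vapply(layers, `[[`, "", "name"), collapse = " & ")
  binary_layer(g, v, name = name)
}

#' Area of a mask in km2
#'
#' Sum of per-cell area weights over true cells, optionally restricted to
#' a second mask. This is the numerator and denominator of every coverage
#' and representativeness rate.
#'
#' @param layer a `binary_layer`.
#' @param within optional `binary_layer`; only cells true in both count.
#' @return area in km2 (scalar).
#' @export
mask_area <- function(layer, within = NULL) {
  stopifnot(inherits(layer, "binary_layer"))
  v <- layer$values
  if (!is.null(within)) {
    if (!same_grid(layer$grid, within$grid))
      stop("mask_area: 'within' is on a different grid")
    v <- v & within$values
  }
  sum(cell_areas(layer$grid)[v])
}

zone_cells <- function(zones) {
  idx <- which(!is.na(zones$zone_id))
  split(idx, zones$zone_id[idx])
}

#' Area-weighted zonal mean of a continuous layer
#'
#' @param layer a `continuous_layer`.
#' @param zones a `zone_partition` on the same grid.
#' @return data.frame with `zone_id`, `name`, `mean`, `n_cells`,
#'   `defined`; zones with no valid cell have `mean = NA` and
#'   `defined = FALSE`.
#' @export
zonal_mean <- function(layer, zones) {
  stopifnot(inherits(layer, "continuous_layer"),
            inherits(zones, "zone_partition"))
  if (!same_grid(layer$grid, zones$grid))
    stop("zonal_mean: layer and zones on different grids")
  w <- cell_areas(layer$grid)
  tab <- zones$zone_table
  out <- data.frame(zone_id = tab$zone_id, name = tab$name,
                    mean = NA_real_, n_cells = 0L, defined = FALSE,
                    stringsAsFactors = FALSE)
  cells <- zone_cells(zones)
  for (i in seq_len(nrow(out))) {
    idx <- cells[[as.character(out$zone_id[i])]]
    if (is.null(idx)) next
    v <- layer$values[idx]
    ok <- !is.na(v)
    out$n_cells[i] <- sum(ok)
    if (any(ok)) {
      out$mean[i] <- sum(v[ok] * w[idx][ok]) / sum(w[idx][ok])
      out$defined[i] <- TRUE
    }
  }
  out
}

#' Percent of each zone covered by a mask
#'
#' `100 * area(mask & zone) / area(zone)` per zone, on the 0-100 scale.
#'
#' @param mask a `binary_layer`.
#' @param zones a `zone_partition` on the same grid.
#' @return data.frame with `zone_id`, `name`, `percent`, `defined`.
#' @export
zonal_fraction <- function(mask, zones) {
  stopifnot(inherits(mask, "binary_layer"),
            inherits(zones, "zone_partition"))
  if (!same_grid(mask$grid, zones$grid))
    stop("zonal_fraction: mask and zones on different grids")
  w <- cell_areas(mask$grid)
  tab <- zones$zone_table
  out <- data.frame(zone_id = tab$zone_id, name = tab$name,
                    percent = NA_real_, defined = FALSE,
                    stringsAsFactors = FALSE)
  cells <- zone_cells(zones)
  for (i in seq_len(nrow(out))) {
    idx <- cells[[as.character(out$zone_id[i])]]
    if (is.null(idx)) next
    denom <- sum(w[idx])
    if (denom > 0) {
      out$percent[i] <- 100 * sum(w[idx][mask$values[idx]]) / denom
      out$defined[i] <- TRUE
    }
  }
  out
}
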