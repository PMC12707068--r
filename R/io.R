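#' Write a layer as a plain-text grid (CSV)
#'
#' One row per grid row (top row first), comma-separated, missing cells
#' empty. Binary layers are written as 0/1. The companion
#' [read_layer_csv] restores the layer onto a given grid.
#'
#' @param layer a `binary_layer` or `continuous_layer`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_layer_csv <- function(layer, path) {
  m <- if (inherits(layer, "binary_layer")) layer$values * 1L else layer$values
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}

#' Read a plain-text grid back onto a grid
#' @param path file written by [write_layer_csv].
#' @param grid the [grid_spec] the layer lives on.
#' @param type "continuous" or "binary".
#' @param name layer label.
#' @return a `continuous_layer` or `binary_layer`.
#' @export
read_layer_csv <- function(path, grid, type = c("continuous", "binary"),
                           name = basename(path)) {
  type <- match.arg(type)
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   na.strings = ""))
  dimnames(m) <- NULL
  if (type == "binary") binary_layer(grid, m == 1, name = name)
  else continuous_layer(grid, m, name = name)
}

#' Write a [0, 1] layer as a single-band 32-bit TIFF
#'
#' Suitable for quality, standardized CVI and binary masks; missing
#' cells are written as 0 (the land mask defines validity).
#'
#' @param layer a `binary_layer` or `continuous_layer` with values in
#'   [0, 1].
#' @param path output .tif file.
#' @return `path`, invisibly.
#' @export
write_layer_tiff <- function(layer, path) {
  m <- if (inherits(layer, "binary_layer")) layer$values * 1 else layer$values
  m[is.na(m)] <- 0
  if (min(m) < 0 || max(m) > 1)
    stop("TIFF export supports values in [0, 1]; rescale or use write_layer_csv")
  tiff::writeTIFF(m, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write reserve records as the tabular CSV interchange format
#'
#' Columns: id, network, lon, lat, area_km2, year, region, country,
#' status, desig, geometry (WKT POLYGON, empty for buffer-only
#' records). [load_reserves] reads this format back.
#'
#' @param records list of `reserve_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reserves_csv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(id = r$id, network = r$network,
               lon = r$centroid[1L], lat = r$centroid[2L],
               area_km2 = r$terrestrial_area, year = r$designation_year,
               region = r$region, country = r$country, status = r$status,
               desig = r$desig_label,
               geometry = if (is.null(r$geometry)) ""
                          else polygon_to_wkt(r$geometry),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
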