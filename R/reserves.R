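#' Construct a reserve record
#'
#' One reserve in one of the three networks: BR (biosphere reserve), PA
#' (protected area) or OECM. Geometry may be a polygon or absent, in
#' which case a circular buffer sized from the terrestrial area stands in
#' (see [circular_buffer]).
#'
#' @param id reserve identifier.
#' @param network one of "BR", "PA", "OECM".
#' @param centroid numeric (x, y) in map units.
#' @param terrestrial_area km2, >= 0.
#' @param designation_year integer year (>= 1800).
#' @param region,country,status,desig_label attribute strings.
#' @param geometry optional [sc_polygon].
#' @param ecosystem_group optional label (Forest, Grassland,
#'   Polar & Tundra, Desert, Ocean, Freshwater).
#' @return An object of class `reserve_record`.
#' @export
reserve_record <- function(id, network, centroid, terrestrial_area,
                           designation_year, region = NA_character_,
                           country = NA_character_, status = "designated",
                           desig_label = NA_character_, geometry = NULL,
                           ecosystem_group = NA_character_) {
  network <- match.arg(network, c("BR", "PA", "OECM"))
  stopifnot(length(centroid) == 2L, terrestrial_area >= 0)
  designation_year <- as.integer(designation_year)
  if (is.na(designation_year) || designation_year < 1800L)
    stop("designation_year must be a plausible year (>= 1800)")
  if (!is.null(geometry) && !inherits(geometry, "sc_polygon"))
    stop("geometry must be an sc_polygon or NULL")
  structure(list(id = as.character(id), network = network,
                 centroid = as.numeric(centroid),
                 terrestrial_area = terrestrial_area,
                 designation_year = designation_year,
                 region = region, country = country, status = status,
                 desig_label = desig_label, geometry = geometry,
                 ecosystem_group = ecosystem_group),
            class = "reserve_record")
}

#' @export
print.reserve_record <- function(x, ...) {
  cat(sprintf("reserve_record %s [%s]: %g km2, designated %d, %s\n",
              x$id, x$network, x$terrestrial_area, x$designation_year,
              if (is.null(x$geometry)) "buffer-only" else "polygon"))
  invisible(x)
}

#' Load reserve records from a table, applying exclusion rules
#'
#' Reads the tabular reserve source (the analogue of a WDPA/WDOECM
#' extract plus the biosphere-reserve register) and drops records the
#' accounting must not double count: protected-area records that merely
#' mirror a MAB listing (designation label "MAB") and sites whose status
#' is "proposed" rather than designated. Rules are checked independently
#' of each other, so the surviving set does not depend on rule order.
#'
#' @param table data.frame with columns `id`, `network`, `lon`, `lat`,
#'   `area_km2`, `year`, `region`, `country`, `status`, `desig`, and
#'   optionally `geometry` (WKT POLYGON or empty string).
#' @param rules list with `exclude_status` (status values to drop, case
#'   insensitive; default "proposed") and `exclude_mab_desig_networks`
#'   (networks from which desig-label "MAB" records are dropped; default
#'   c("PA", "OECM")).
#' @return list with `records` (list of `reserve_record`), `exclusions`
#'   (data.frame id, network, rule) and `counts` (per-rule tally).
#' @export
load_reserves <- function(table,
                          rules = list(
                            exclude_status = "proposed",
                            exclude_mab_desig_networks = c("PA", "OECM"))) {
  mandatory <- c("id", "network", "lon", "lat", "area_km2", "year",
                 "region", "country", "status", "desig")
  missing <- setdiff(mandatory, names(table))
  if (length(missing))
    stop("reserve table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  has_geom <- "geometry" %in% names(table)

  status <- tolower(trimws(as.character(table$status)))
  desig <- toupper(trimws(as.character(table$desig)))
  status[is.na(status)] <- ""
  desig[is.na(desig)] <- ""
  rule_status <- status %in% tolower(rules$exclude_status)
  rule_mab <- desig == "MAB" &
    table$network %in% rules$exclude_mab_desig_networks

  excl <- data.frame(id = character(), network = character(),
                     rule = character(), stringsAsFactors = FALSE)
  if (any(rule_status))
    excl <- rbind(excl, data.frame(id = as.character(table$id[rule_status]),
                                   network = table$network[rule_status],
                                   rule = "status_proposed"))
  if (any(rule_mab))
    excl <- rbind(excl, data.frame(id = as.character(table$id[rule_mab]),
                                   network = table$network[rule_mab],
                                   rule = "desig_mab"))
  keep <- !(rule_status | rule_mab)

  records <- lapply(which(keep), function(i) {
    geom <- NULL
    if (has_geom) {
      w <- table$geometry[i]
      if (!is.na(w) && nzchar(trimws(w))) {
        geom <- wkt_to_polygon(w)
        if (is_empty_polygon(geom)) geom <- NULL
      }
    }
    reserve_record(id = table$id[i], network = table$network[i],
                   centroid = c(table$lon[i], table$lat[i]),
                   terrestrial_area = table$area_km2[i],
                   designation_year = table$year[i],
                   region = as.character(table$region[i]),
                   country = as.character(table$country[i]),
                   status = as.character(table$status[i]),
                   desig_label = as.character(table$desig[i]),
                   geometry = geom)
  })
  list(records = records, exclusions = excl,
       counts = c(status_proposed = sum(rule_status),
                  desig_mab = sum(rule_mab), retained = sum(keep)))
}

#' Circular-buffer footprint for a reserve without a polygon
#'
#' Reserves lacking boundary polygons get a disc centered on their
#' coordinates with radius `sqrt(terrestrial_area / pi)`, so the buffer
#' area equals the reported terrestrial area. Map units are assumed
#' consistent with the grid's km2 cell areas.
#'
#' @param record a `reserve_record` with no geometry and positive area.
#' @param n vertices of the approximating polygon (default 64).
#' @return An [sc_polygon] disc.
#' @examples
#' r <- reserve_record("x", "BR", c(50, 50), terrestrial_area = pi,
#'                     designation_year = 2000)
#' # radius 1 disc:
#' polygon_area(circular_buffer(r))
#' @export
circular_buffer <- function(record, n = 64L) {
  stopifnot(inherits(record, "reserve_record"))
  if (!is.null(record$geometry))
    stop("record already has a polygon geometry")
  if (record$terrestrial_area <= 0)
    stop("circular_buffer requires terrestrial_area > 0")
  disc_polygon(record$centroid, record$terrestrial_area, n = n)
}

#' Resolve geometries for a list of records
#'
#' Polygons pass through untouched; buffer-only records receive their
#' circular buffer. Buffers are not clipped to land here — coverage
#' accounting intersects with the land mask at rasterization time.
#'
#' @param records list of `reserve_record`.
#' @return the list with every record carrying a geometry.
#' @export
resolve_geometries <- function(records) {
  lapply(records, function(rec) {
    if (is.null(rec$geometry)) rec$geometry <- circular_buffer(rec)
    rec
  })
}

#' Dominant-biome ecosystem classification
#'
#' Assigns a reserve the ecosystem group of the biome holding the
#' largest area share of its footprint; exact ties go to the lowest
#' biome id (deterministic).
#'
#' @param record a `reserve_record` with resolved geometry.
#' @param biomes a `zone_partition` of biome ids.
#' @param mapping data.frame with columns `zone_id` and `group` covering
#'   every biome id.
#' @return the group label (character), or `NA` with a warning when the
#'   footprint rasterizes to zero biome cells.
#' @export
classify_ecosystem <- function(record, biomes, mapping) {
  stopifnot(inherits(record, "reserve_record"),
            inherits(biomes, "zone_partition"))
  if (is.null(record$geometry))
    stop("record geometry must be resolved before classification")
  if (!all(c("zone_id", "group") %in% names(mapping)))
    stop("mapping needs columns 'zone_id' and 'group'")
  ids_present <- biomes$zone_table$zone_id
  if (!all(ids_present %in% mapping$zone_id))
    stop("mapping does not cover biome id(s): ",
         paste(setdiff(ids_present, mapping$zone_id), collapse = ", "))
  fp <- rasterize_polygon(record$geometry, biomes$grid, name = record$id)
  idx <- which(fp$values & !is.na(biomes$zone_id))
  if (!length(idx)) {
    warning("footprint of ", record$id, " rasterizes to zero biome cells")
    return(NA_character_)
  }
  w <- cell_areas(biomes$grid)[idx]
  a <- tapply(w, biomes$zone_id[idx], sum)
  best <- as.integer(names(a)[a == max(a)])
  mapping$group[match(min(best), mapping$zone_id)]
}

#' Rasterized union footprint of one network
#'
#' Builds the network's binary layer as the union of its members'
#' rasterized footprints, intersected with land. Overlapping members are
#' counted once.
#'
#' @param records list of `reserve_record` (mixed networks allowed).
#' @param network which network to extract ("BR", "PA" or "OECM").
#' @param grid a [grid_spec].
#' @return list of class `reserve_network_layer` with `network`,
#'   `members` (ids) and `mask` (`binary_layer`).
#' @export
network_mask <- function(records, network, grid) {
  network <- match.arg(network, c("BR", "PA", "OECM"))
  members <- Filter(function(r) r$network == network, records)
  v <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (rec in members) {
    if (is.null(rec$geometry))
      stop("member ", rec$id, " has unresolved geometry; run resolve_geometries()")
    v <- v | rasterize_polygon(rec$geometry, grid, terrestrial = FALSE)$values
  }
  structure(list(network = network,
                 members = vapply(members, `[[`, "", "id"),
                 mask = binary_layer(grid, v, name = network)),
            class = "reserve_network_layer")
}

#' @export
print.reserve_network_layer <- function(x, ...) {
  cat(sprintf("reserve_network_layer %s: %d members, area %g km2\n",
              x$network, length(x$members), mask_area(x$mask)))
  invisible(x)
}
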