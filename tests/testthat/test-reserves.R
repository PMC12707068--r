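reserve_table <- function() {
  data.frame(
    id = c("p1", "p2", "p3", "b1"),
    network = c("PA", "PA", "PA", "BR"),
    lon = c(5, 6, 7, 8), lat = c(5, 6, 7, 8),
    area_km2 = c(10, 12, 9, 20), year = c(1990, 2001, 2010, 1985),
    region = "Africa", country = "X",
    status = c("designated", "Proposed", "designated", "designated"),
    desig = c("National Park", "National Park", "MAB", "MAB"),
    geometry = c("POLYGON ((4 4, 6 4, 6 6, 4 6, 4 4))", "", "", ""),
    stringsAsFactors = FALSE)
}

test_that("exclusion rules drop proposed sites and MAB-labelled PAs", {
  res <- load_reserves(reserve_table())
  ids <- vapply(res$records, `[[`, "", "id")
  expect_setequal(ids, c("p1", "b1"))       # p2: proposed; p3: PA with MAB desig
  expect_equal(unname(res$counts["status_proposed"]), 1)
  expect_equal(unname(res$counts["desig_mab"]), 1)
  # BR with MAB designation label is retained: the rule targets PA/OECM rows
  expect_true("b1" %in% ids)
  # valid polygon passes through
  p1 <- res$records[[which(ids == "p1")]]
  expect_s3_class(p1$geometry, "sc_polygon")
  expect_equal(polygon_area(p1$geometry), 4)
})

test_that("exclusion rules are order-independent and name missing columns", {
  tab <- reserve_table()
  r1 <- load_reserves(tab, rules = list(exclude_status = "proposed",
                                        exclude_mab_desig_networks = c("PA", "OECM")))
  r2 <- load_reserves(tab, rules = list(exclude_mab_desig_networks = c("PA", "OECM"),
                                        exclude_status = "proposed"))
  expect_identical(vapply(r1$records, `[[`, "", "id"),
                   vapply(r2$records, `[[`, "", "id"))
  expect_error(load_reserves(tab[, setdiff(names(tab), "status")]), "status")
})

test_that("circular buffers have the closed-form radius and exact area", {
  r <- reserve_record("x", "BR", c(50, 50), terrestrial_area = pi,
                      designation_year = 2000)
  buf <- circular_buffer(r)
  expect_equal(polygon_area(buf), pi, tolerance = 1e-12)
  # mean vertex distance from center ~ radius 1 (n-gon slightly inflated)
  radii <- sqrt(rowSums(sweep(buf$rings[[1]], 2, c(50, 50))^2))
  expect_equal(mean(radii), 1, tolerance = 0.01)

  r100 <- reserve_record("y", "BR", c(0, 0), terrestrial_area = 100,
                         designation_year = 2000)
  radii100 <- sqrt(rowSums(circular_buffer(r100)$rings[[1]]^2))
  expect_equal(mean(radii100), sqrt(100 / pi), tolerance = 0.05)
  expect_equal(sqrt(100 / pi), 5.64190, tolerance = 1e-5)

  r0 <- reserve_record("z", "BR", c(0, 0), terrestrial_area = 0,
                       designation_year = 2000)
  expect_error(circular_buffer(r0), "terrestrial_area > 0")
})

test_that("rasterized buffers recover the target area within 5% at >= 20-cell diameters", {
  area <- pi * 12^2  # diameter 24 cells
  g <- grid_spec(60, 60)
  rec <- reserve_record("b", "BR", c(30, 30), terrestrial_area = area,
                        designation_year = 2000)
  fp <- rasterize_polygon(circular_buffer(rec), g)
  err1 <- abs(mask_area(fp) - area) / area
  expect_lt(err1, 0.05)
  # refinement halves the cell size: error does not grow
  g2 <- grid_spec(120, 120, cell_size = 0.5, cell_area = 0.25)
  fp2 <- rasterize_polygon(circular_buffer(rec), g2)
  err2 <- abs(mask_area(fp2) - area) / area
  expect_lt(err2, err1 + 1e-9)
})

test_that("dominant-biome classification uses largest share with low-id tie-break", {
  g <- grid_spec(10, 10)
  zid <- matrix(2L, 10, 10); zid[, 1:4] <- 1L   # 40% biome 1, 60% biome 2
  biomes <- zone_partition(g, zid)
  mapping <- data.frame(zone_id = 1:2, group = c("Grassland", "Forest"))
  rec <- reserve_record("r", "BR", c(5, 5), terrestrial_area = 100,
                        designation_year = 2000,
                        geometry = sc_polygon(cbind(c(0, 10, 10, 0),
                                                    c(0, 0, 10, 10))))
  expect_equal(classify_ecosystem(rec, biomes, mapping), "Forest")

  # footprint entirely in one biome
  rec2 <- reserve_record("r2", "BR", c(2, 5), terrestrial_area = 4,
                         designation_year = 2000,
                         geometry = sc_polygon(cbind(c(1, 3, 3, 1),
                                                     c(4, 4, 6, 6))))
  expect_equal(classify_ecosystem(rec2, biomes, mapping), "Grassland")

  # exact 50/50 tie: group of the lower biome id (brute-force: cells split 10/10)
  rec3 <- reserve_record("r3", "BR", c(4, 5), terrestrial_area = 20,
                         designation_year = 2000,
                         geometry = sc_polygon(cbind(c(2, 6, 6, 2),
                                                     c(2, 2, 7, 7))))
  fp <- rasterize_polygon(rec3$geometry, g)
  expect_equal(sum(fp$values & zid == 1L), sum(fp$values & zid == 2L))
  expect_equal(classify_ecosystem(rec3, biomes, mapping), "Grassland")

  # zero-cell footprint flagged undefined
  tiny <- reserve_record("r4", "BR", c(0.98, 0.98), terrestrial_area = 0.001,
                         designation_year = 2000,
                         geometry = sc_polygon(cbind(c(0.96, 1.0, 1.0, 0.96),
                                                     c(0.96, 0.96, 1.0, 1.0))))
  expect_warning(out <- classify_ecosystem(tiny, biomes, mapping), "zero")
  expect_true(is.na(out))
})

test_that("network masks union member footprints, counting overlaps once", {
  g <- grid_spec(20, 20)
  sq <- function(x0, y0, s) sc_polygon(cbind(c(x0, x0 + s, x0 + s, x0),
                                             c(y0, y0, y0 + s, y0 + s)))
  recs <- list(
    reserve_record("a", "PA", c(5, 5), 16, 2000, geometry = sq(3, 3, 4)),
    reserve_record("b", "PA", c(7, 5), 16, 2000, geometry = sq(5, 3, 4)),
    reserve_record("c", "BR", c(15, 15), 4, 2000, geometry = sq(14, 14, 2)))
  nm <- network_mask(recs, "PA", g)
  # overlap cells counted once: brute-force per-cell membership scan
  scan <- rasterize_polygon(sq(3, 3, 4), g)$values |
    rasterize_polygon(sq(5, 3, 4), g)$values
  expect_equal(nm$mask$values, scan)
  expect_equal(mask_area(nm$mask), sum(scan))
  expect_lt(mask_area(nm$mask), 32)  # strict: overlap not double counted

  # empty network -> all-false mask
  expect_equal(sum(network_mask(recs, "OECM", g)$mask$values), 0)

  # tri-network union consistency
  u3 <- union_masks(network_mask(recs, "BR", g)$mask,
                    network_mask(recs, "PA", g)$mask,
                    network_mask(recs, "OECM", g)$mask)
  all_fp <- scan | rasterize_polygon(sq(14, 14, 2), g)$values
  expect_equal(u3$values, all_fp)
})
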