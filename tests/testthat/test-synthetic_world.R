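test_that("generation is fully deterministic under the root seed", {
  cfg <- small_world_cfg(seed = 19, n = 40)
  w1 <- gen_synthetic_world(cfg)
  w2 <- gen_synthetic_world(cfg)
  expect_identical(w1$grid$land, w2$grid$land)
  expect_identical(w1$provinces$zone_id, w2$provinces$zone_id)
  expect_identical(lapply(w1$templates$templates, function(t) t$mask$values),
                   lapply(w2$templates$templates, function(t) t$mask$values))
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$quality$layers[["2005"]]$values,
                   w2$quality$layers[["2005"]]$values)
  # a different seed changes the world
  w3 <- gen_synthetic_world(small_world_cfg(seed = 20, n = 40))
  expect_false(identical(w1$grid$land, w3$grid$land))
})

test_that("land fraction, degenerate configs and province partitions", {
  cfg <- world_config(n_rows = 30, n_cols = 30, land_fraction = 0.4,
                      n_provinces = 5, seed = 2)
  w <- gen_world(cfg)
  expect_lte(abs(sum(w$grid$land) - 0.4 * 900), 1)

  # land fraction 1: full grid
  w_full <- gen_world(world_config(n_rows = 10, n_cols = 10,
                                   land_fraction = 1, n_provinces = 1,
                                   seed = 1))
  expect_true(all(w_full$grid$land))
  # single province covers all land
  expect_equal(unique(as.vector(w_full$provinces$zone_id)), 1L)

  # impossible config rejected
  expect_error(gen_world(world_config(n_rows = 3, n_cols = 3,
                                      land_fraction = 0.3,
                                      n_provinces = 50, seed = 1)),
               "impossible")
})

test_that("template masks hit their target shares within one percentage point", {
  for (s in 1:3) {
    cfg <- small_world_cfg(seed = s, n = 50)
    w <- gen_world(cfg)
    tpl <- gen_templates(cfg, w)
    expect_true(all(abs(tpl$realized_shares - cfg$template_shares) <= 0.011),
                info = paste("seed", s))
    # i.i.d. threshold (no smoothing) also respects the share
    cfg0 <- world_config(n_rows = 50, n_cols = 50, template_autocorr = 0,
                         seed = s)
    t0 <- gen_templates(cfg0, gen_world(cfg0))
    expect_true(all(abs(t0$realized_shares - cfg0$template_shares) <= 0.011))
  }
})

test_that("reserve generation: disjoint networks at overlap zero, buffers on demand", {
  cfg <- world_config(
    n_rows = 60, n_cols = 60, land_fraction = 0.5, n_provinces = 6,
    reserves = list(
      PA = list(count = 10, meanlog = log(10), sdlog = 0.5, min_area = 4,
                frac_no_polygon = 0, target_overlap = 0),
      BR = list(count = 8, meanlog = log(8), sdlog = 0.5, min_area = 4,
                frac_no_polygon = 1, target_overlap = 0)),
    seed = 5)
  w <- gen_world(cfg)
  res <- gen_reserves(cfg, w)
  nm <- res$truth$network_masks
  # overlap target 0: pairwise intersection area is exactly zero
  expect_equal(mask_area(nm$PA, within = nm$BR), 0)
  # polygon-free fraction 1: every BR record requires buffering
  br_recs <- Filter(function(r) r$network == "BR", res$records)
  expect_true(all(vapply(br_recs, function(r) is.null(r$geometry), TRUE)))
  # truth areas match a per-cell recount of resolved footprints
  resolved <- resolve_geometries(res$records)
  for (rec in resolved) {
    fp <- rasterize_polygon(rec$geometry, w$grid)
    truth_row <- res$truth$reserves[res$truth$reserves$id == rec$id, ]
    expect_equal(mask_area(fp), truth_row$area_land_km2)
  }
})

test_that("achieved inter-network overlap tracks the target", {
  cfg <- world_config(
    n_rows = 80, n_cols = 80, land_fraction = 0.5, n_provinces = 6,
    reserves = list(
      PA = list(count = 40, meanlog = log(20), sdlog = 0.4, min_area = 4,
                frac_no_polygon = 0, target_overlap = 0),
      BR = list(count = 30, meanlog = log(10), sdlog = 0.4, min_area = 4,
                frac_no_polygon = 0.3, target_overlap = 0.3)),
    seed = 9)
  res <- gen_reserves(cfg, gen_world(cfg))
  expect_lt(abs(res$truth$achieved_overlap[["BR"]] - 0.3), 0.05)
})

test_that("quality stacks carry the configured trends with exact noiseless recovery", {
  cfg <- world_config(
    n_rows = 40, n_cols = 40, land_fraction = 0.6, n_provinces = 4,
    reserves = list(BR = list(count = 6, meanlog = log(15), sdlog = 0.4,
                              min_area = 6, frac_no_polygon = 0,
                              target_overlap = 0)),
    trend = list(breaks = default_breaks(),
                 slope_mean = c(1e-3, -2e-3, -1e-3),
                 slope_sd = c(5e-4, 5e-4, 5e-4),
                 noise_sd = 0, base = 0.6, base_amplitude = 0.05),
    seed = 12)
  w <- gen_world(cfg)
  res <- gen_reserves(cfg, w)
  qs <- gen_quality_stack(cfg, w, res$records)
  # all quality values in [0, 1]
  for (l in qs$stack$layers) {
    v <- l$values[!is.na(l$values)]
    expect_true(all(v >= 0 & v <= 1))
  }
  # noiseless: fitted sub-period slopes equal the recorded true slopes exactly
  resolved <- resolve_geometries(res$records)
  for (i in seq_along(resolved)) {
    s <- reserve_series(resolved[[i]], qs$stack)
    if (!s$defined) next
    fits <- piecewise_trend(s$values)
    tr <- qs$true_slopes[qs$true_slopes$id == resolved[[i]]$id, ]
    done <- !fits$skipped & fits$period_lo >= s$start_year
    expect_equal(fits$slope[done],
                 as.numeric(tr[, -1])[done], tolerance = 1e-9)
  }

  # zero slope + zero noise: constant stack
  cfg0 <- cfg
  cfg0$trend$slope_mean <- c(0, 0, 0); cfg0$trend$slope_sd <- c(0, 0, 0)
  qs0 <- gen_quality_stack(cfg0, w, res$records)
  expect_identical(qs0$stack$layers[[1]]$values,
                   qs0$stack$layers[[29]]$values)
})

test_that("world truth coverage matches the coverage module exactly", {
  w <- gen_synthetic_world(small_world_cfg(seed = 23, n = 50))
  nm <- w$truth$network_masks
  pa_oecm <- union_masks(nm$PA, nm$OECM)
  rep <- coverage_report(pa_oecm, nm$BR)
  expect_identical(rep$pct_without, unname(w$truth$coverage$global["pct_without"]))
  expect_identical(rep$pct_with, unname(w$truth$coverage$global["pct_with"]))
  strat <- coverage_report(pa_oecm, nm$BR, w$provinces)
  expect_equal(strat$pct_without, unname(w$truth$coverage$province[, "pct_without"]))
  expect_equal(strat$pct_with, unname(w$truth$coverage$province[, "pct_with"]))
})
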