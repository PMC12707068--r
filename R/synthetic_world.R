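#' Configuration for a synthetic world
#'
#' Defines the study conditions for a fully synthetic run: grid shape
#' and land fraction, zone partitions (biogeographic provinces, the five
#' world regions, six biomes), six binary opportunity templates with
#' target land-area shares and spatial autocorrelation, three reserve
#' networks with size distributions, polygon-free fractions and
#' controlled inter-network overlap, and annual quality layers carrying
#' known piecewise trends. Template share targets follow the printed
#' global shares where available (hotspots ~2.5% of land, phylogenetic
#' 12.86%, functional 14.47%); the remaining shares are set so the risk
#' ecoregions are the largest template and indigenous lands the second
#' largest, matching their qualitative ranking.
#'
#' @param n_rows,n_cols grid shape (default 100 x 100).
#' @param land_fraction fraction of cells that are land (default 0.3).
#' @param n_provinces,n_regions,n_biomes zone counts (default 20, 5, 6).
#' @param template_shares named target shares in (0, 1).
#' @param template_autocorr smoothing length in cells (default 5).
#' @param reserves per-network specs, a named list (generation order =
#'   list order) of lists with `count`, `meanlog`/`sdlog` (log-normal
#'   footprint areas, km2), `min_area`, `frac_no_polygon` (fraction
#'   emitted as centroid+area only), `target_overlap` (fraction of the
#'   network's area overlapping previously generated networks).
#' @param year_range designation years sampled uniformly (default
#'   1976-2015).
#' @param years stack years (default 1992:2020).
#' @param trend list: `breaks` (sub-periods), `slope_mean`/`slope_sd`
#'   per sub-period (quality units/year), `noise_sd` (cell-level
#'   Gaussian noise), `base` (background quality), `base_amplitude`
#'   (spatial variation of the background).
#' @param pressure_range range of the smooth pressure surface (default
#'   c(0, 50), Human-Footprint-like).
#' @param seed integer root seed; all generator randomness derives from
#'   it through fixed substreams.
#' @return list of class `world_config`.
#' @export
world_config <- function(n_rows = 100L, n_cols = 100L,
                         land_fraction = 0.3,
                         n_provinces = 20L, n_regions = 5L, n_biomes = 6L,
                         template_shares = c(BH = 0.025, RE = 0.30,
                                             PD = 0.1286, TF = 0.1447,
                                             BC = 0.20, IL = 0.25),
                         template_autocorr = 5,
                         reserves = list(
                           PA = list(count = 30L, meanlog = log(12),
                                     sdlog = 0.7, min_area = 4,
                                     frac_no_polygon = 0,
                                     target_overlap = 0),
                           OECM = list(count = 8L, meanlog = log(8),
                                       sdlog = 0.6, min_area = 4,
                                       frac_no_polygon = 0,
                                       target_overlap = 0.1),
                           BR = list(count = 18L, meanlog = log(6),
                                     sdlog = 0.8, min_area = 4,
                                     frac_no_polygon = 0.26,
                                     target_overlap = 0.35)),
                         year_range = c(1976L, 2015L),
                         years = 1992:2020,
                         trend = list(breaks = default_breaks(),
                                      slope_mean = c(1e-3, -2e-3, -1e-3),
                                      slope_sd = c(5e-4, 5e-4, 5e-4),
                                      noise_sd = 0.02, base = 0.6,
                                      base_amplitude = 0.1),
                         pressure_range = c(0, 50),
                         seed = 1L) {
  stopifnot(land_fraction > 0, land_fraction <= 1,
            all(template_shares > 0), all(template_shares < 1),
            n_provinces >= 1, length(seed) == 1L)
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              land_fraction = land_fraction,
              n_provinces = as.integer(n_provinces),
              n_regions = as.integer(n_regions),
              n_biomes = as.integer(n_biomes),
              template_shares = template_shares,
              template_autocorr = template_autocorr,
              reserves = reserves, year_range = as.integer(year_range),
              years = as.integer(years), trend = trend,
              pressure_range = pressure_range, seed = as.integer(seed))
  class(cfg) <- "world_config"
  cfg
}

# fixed per-component substreams so adding a component never perturbs others
substream_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) + 99991 * k) %% 2147483647)
}

with_substream <- function(seed, k, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(substream_seed(seed, k))
  expr
}

# moving average with shrinking windows at the edges (cumsum trick)
blur1d <- function(v, half) {
  n <- length(v)
  cs <- c(0, cumsum(v))
  hi <- pmin(seq_len(n) + half, n)
  lo <- pmax(seq_len(n) - half, 1L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smoothed Gaussian noise field
#' @param n_rows,n_cols shape.
#' @param autocorr smoothing length in cells (0 = i.i.d. noise).
#' @param passes box-blur passes (3 approximates a Gaussian kernel).
#' @return numeric matrix (uses the current RNG stream).
#' @export
smooth_noise <- function(n_rows, n_cols, autocorr = 0, passes = 3L) {
  m <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  half <- as.integer(ceiling(autocorr))
  if (half > 0) {
    for (i in seq_len(passes)) {
      m <- apply(m, 2L, blur1d, half = half)
      m <- t(apply(m, 1L, blur1d, half = half))
    }
  }
  m
}

# select the top-k land cells of a score field so the selected area hits
# `target_area` (ties broken by score then cell index: deterministic)
select_top_area <- function(score, land, w, target_area) {
  idx <- which(land)
  o <- idx[order(score[idx], idx, decreasing = c(TRUE, FALSE),
                 method = "radix")]
  cum <- cumsum(w[o])
  k <- which(cum >= target_area)[1L]
  if (is.na(k)) k <- length(o)
  sel <- matrix(FALSE, nrow(score), ncol(score))
  sel[o[seq_len(k)]] <- TRUE
  sel
}

# contiguous zones by seeded multi-source region growth; disconnected
# land components with no seed fall back to nearest-seed assignment
grow_partition <- function(land, n_zones) {
  nr <- nrow(land); nc <- ncol(land)
  land_idx <- which(land)
  if (n_zones > length(land_idx))
    stop("impossible config: more zones than land cells")
  zone <- matrix(NA_integer_, nr, nc)
  seeds <- sample(land_idx, n_zones)
  zone[seeds] <- seq_len(n_zones)
  frontier <- seeds
  while (length(frontier)) {
    frontier <- frontier[sample.int(length(frontier))]
    nxt <- integer(0)
    for (cell in frontier) {
      r <- ((cell - 1L) %% nr) + 1L
      c <- ((cell - 1L) %/% nr) + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1L] < 1L || d[1L] > nr || d[2L] < 1L || d[2L] > nc) next
        j <- (d[2L] - 1L) * nr + d[1L]
        if (land[j] && is.na(zone[j])) {
          zone[j] <- zone[cell]
          nxt <- c(nxt, j)
        }
      }
    }
    frontier <- nxt
  }
  orphans <- land_idx[is.na(zone[land_idx])]
  if (length(orphans)) {
    sr <- ((seeds - 1L) %% nr) + 1L; sc <- ((seeds - 1L) %/% nr) + 1L
    for (cell in orphans) {
      r <- ((cell - 1L) %% nr) + 1L; c <- ((cell - 1L) %/% nr) + 1L
      zone[cell] <- zone[seeds[which.min((sr - r)^2 + (sc - c)^2)]]
    }
  }
  zone
}

#' Generate the grid, land mask and zone partitions
#'
#' Land is the top `land_fraction` of an autocorrelated noise field
#' (requested fraction hit to within one cell); provinces, regions and
#' biomes are contiguous partitions grown from random seed cells.
#'
#' @param cfg a [world_config].
#' @return list with `grid` ([grid_spec]), `land` (`binary_layer`),
#'   `provinces`, `regions`, `biomes` (`zone_partition`s).
#' @export
gen_world <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  nr <- cfg$n_rows; nc <- cfg$n_cols
  land <- with_substream(cfg$seed, 1L, {
    if (cfg$land_fraction >= 1) matrix(TRUE, nr, nc)
    else {
      score <- smooth_noise(nr, nc, autocorr = 4)
      k <- round(cfg$land_fraction * nr * nc)
      sel <- matrix(FALSE, nr, nc)
      sel[order(score, decreasing = TRUE)[seq_len(k)]] <- TRUE
      sel
    }
  })
  grid <- grid_spec(nr, nc, cell_size = 1, cell_area = 1, land = land)
  regions5 <- c("Africa", "Arab States", "Asia-Pacific",
                "Europe-N.America", "Latin America-Caribbean")
  groups6 <- c("Forest", "Grassland", "Polar & Tundra", "Desert",
               "Ocean", "Freshwater")
  provinces <- with_substream(cfg$seed, 2L,
    zone_partition(grid, grow_partition(land, cfg$n_provinces),
                   data.frame(zone_id = seq_len(cfg$n_provinces),
                              name = sprintf("province_%02d",
                                             seq_len(cfg$n_provinces)))))
  regions <- with_substream(cfg$seed, 3L,
    zone_partition(grid, grow_partition(land, cfg$n_regions),
                   data.frame(zone_id = seq_len(cfg$n_regions),
                              name = regions5[seq_len(cfg$n_regions) %%
                                                length(regions5) + 1L])))
  biomes <- with_substream(cfg$seed, 4L,
    zone_partition(grid, grow_partition(land, cfg$n_biomes),
                   data.frame(zone_id = seq_len(cfg$n_biomes),
                              name = groups6[seq_len(cfg$n_biomes) %%
                                               length(groups6) + 1L])))
  list(grid = grid, land = land_mask(grid), provinces = provinces,
       regions = regions, biomes = biomes)
}

#' Generate the six binary templates at target shares
#'
#' Each mask thresholds an autocorrelated noise field at the
#' area-weighted quantile hitting the target share, so the realized
#' share matches the target to within one cell's area.
#'
#' @param cfg a [world_config].
#' @param world output of [gen_world].
#' @return list: `templates` (a `template_set`) and `realized_shares`.
#' @export
gen_templates <- function(cfg, world) {
  g <- world$grid
  w <- cell_areas(g)
  land_area <- sum(w[g$land])
  ts <- with_substream(cfg$seed, 5L, {
    lapply(seq_along(cfg$template_shares), function(i) {
      score <- smooth_noise(g$n_rows, g$n_cols,
                            autocorr = cfg$template_autocorr)
      sel <- select_top_area(score, g$land, w,
                             cfg$template_shares[i] * land_area)
      template_layer(binary_layer(g, sel,
                                  name = names(cfg$template_shares)[i]))
    })
  })
  ts <- template_set(ts)
  list(templates = ts,
       realized_shares = vapply(ts$templates, `[[`, 0, "p"))
}

# sample a blobby polygon: disc with smooth radial perturbation,
# rescaled to the exact target area
blob_polygon <- function(center, area, n = 48L, roughness = 0.25) {
  r0 <- sqrt(area / pi)
  pert <- blur1d(stats::rnorm(n), half = 6L)
  pert <- pert / max(abs(pert), 1e-9) * roughness
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- r0 * (1 + pert)
  xy <- cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
  poly <- sc_polygon(xy)
  s <- sqrt(area / polygon_area(poly))
  sc_polygon(cbind(center[1L] + (xy[, 1L] - center[1L]) * s,
                   center[2L] + (xy[, 2L] - center[2L]) * s))
}

#' Generate the three reserve networks
#'
#' Networks are generated in the order of `cfg$reserves`. Footprints are
#' blobby polygons (or discs via circular buffering for the configured
#' polygon-free fraction) with log-normal areas. Inter-network overlap
#' is steered by a feedback rule: each new reserve is centered inside
#' the union of earlier networks while the running overlap fraction is
#' below the target, outside it otherwise; a zero target is enforced
#' strictly by rejection-resampling (error if infeasible).
#'
#' @param cfg a [world_config].
#' @param world output of [gen_world].
#' @return list: `records` (mixed polygon / buffer-only
#'   `reserve_record`s), `truth` (per-reserve rasterized land areas,
#'   per-network masks, achieved overlap fractions).
#' @export
gen_reserves <- function(cfg, world) {
  g <- world$grid
  w <- cell_areas(g)
  cc <- cell_centers(g)
  land_idx <- which(g$land)
  records <- list()
  truth_rows <- list()
  net_masks <- list()
  achieved <- list()
  with_substream(cfg$seed, 6L, {
    earlier <- matrix(FALSE, g$n_rows, g$n_cols)
    for (net in names(cfg$reserves)) {
      spec <- cfg$reserves[[net]]
      net_v <- matrix(FALSE, g$n_rows, g$n_cols)
      overlap_area <- 0; net_area <- 0
      for (i in seq_len(spec$count)) {
        area <- max(spec$min_area, stats::rlnorm(1, spec$meanlog, spec$sdlog))
        buffer_only <- stats::runif(1) < spec$frac_no_polygon
        placed <- FALSE
        for (try in seq_len(500L)) {
          if (spec$target_overlap <= 0) {
            cell <- sample(land_idx, 1L)
          } else {
            # pick inside vs outside the earlier union by whichever keeps
            # the running overlap fraction closer to the target (a reserve
            # centered inside overlaps ~70% of its area in practice)
            t_goal <- spec$target_overlap
            f_in <- (overlap_area + 0.7 * area) / (net_area + area)
            f_out <- overlap_area / (net_area + area)
            want_inside <- abs(f_in - t_goal) < abs(f_out - t_goal)
            pool <- if (want_inside && any(earlier)) which(earlier)
                    else if (!want_inside && any(g$land & !earlier))
                      which(g$land & !earlier)
                    else land_idx
            cell <- if (length(pool) == 1L) pool else sample(pool, 1L)
          }
          r <- ((cell - 1L) %% g$n_rows) + 1L
          c <- ((cell - 1L) %/% g$n_rows) + 1L
          center <- c(cc$x[c], cc$y[r])
          geom <- if (buffer_only) disc_polygon(center, area)
                  else blob_polygon(center, area)
          fp <- rasterize_polygon(geom, g, terrestrial = FALSE)$values
          if (spec$target_overlap <= 0 && any(fp & earlier)) next
          placed <- TRUE
          break
        }
        if (!placed)
          stop("overlap target infeasible for network ", net,
               " at the configured density")
        fp_land <- fp & g$land
        net_v <- net_v | fp_land
        net_area <- net_area + sum(w[fp_land])
        overlap_area <- overlap_area + sum(w[fp_land & earlier])
        id <- sprintf("%s_%03d", net, i)
        year <- sample(cfg$year_range[1L]:cfg$year_range[2L], 1L)
        region_id <- world$regions$zone_id[cell]
        rec <- reserve_record(
          id = id, network = net, centroid = center,
          terrestrial_area = area,
          designation_year = year,
          region = world$regions$zone_table$name[
            match(region_id, world$regions$zone_table$zone_id)],
          country = NA_character_, status = "designated",
          desig_label = net,
          geometry = if (buffer_only) NULL else geom)
        records[[id]] <- rec
        truth_rows[[id]] <- data.frame(
          id = id, network = net, designation_year = year,
          area_sampled = area, area_land_km2 = sum(w[fp_land]),
          buffer_only = buffer_only, stringsAsFactors = FALSE)
      }
      net_masks[[net]] <- binary_layer(g, net_v, name = net)
      achieved[[net]] <- if (net_area > 0) overlap_area / net_area else 0
      earlier <- earlier | net_v
    }
  })
  list(records = unname(records),
       truth = list(reserves = do.call(rbind, unname(truth_rows)),
                    network_masks = net_masks,
                    achieved_overlap = unlist(achieved)))
}

#' Generate annual quality layers with known piecewise trends
#'
#' Background quality is a static smooth field around `trend$base`.
#' Inside reserve footprints, a piecewise-linear-in-year signal with
#' per-reserve sub-period slopes is added; cells covered by several
#' reserves follow the first-generated reserve (first claim), and the
#' recorded true slope of each reserve is the area-weighted mean of its
#' footprint cells' slopes, so noiseless recovery is exact even under
#' overlap. Gaussian cell noise is added on top and values clipped to
#' [0, 1].
#'
#' @param cfg a [world_config].
#' @param world output of [gen_world].
#' @param records reserve records (geometry resolved internally).
#' @return list: `stack` (a `quality_stack`), `true_slopes` (data.frame
#'   id x sub-period).
#' @export
gen_quality_stack <- function(cfg, world, records) {
  g <- world$grid
  w <- cell_areas(g)
  tr <- cfg$trend
  breaks <- tr$breaks
  n_per <- length(breaks)
  records <- resolve_geometries(records)
  nrec <- length(records)
  with_substream(cfg$seed, 7L, {
    base <- tr$base + tr$base_amplitude *
      smooth_noise(g$n_rows, g$n_cols, autocorr = 6)
    base <- pmin(pmax(base, 0.05), 0.95)
    slopes <- matrix(stats::rnorm(nrec * n_per,
                                  mean = rep(tr$slope_mean, each = nrec),
                                  sd = rep(tr$slope_sd, each = nrec)),
                     nrec, n_per)
    claim <- matrix(0L, g$n_rows, g$n_cols)
    fps <- vector("list", nrec)
    for (i in seq_len(nrec)) {
      fp <- rasterize_polygon(records[[i]]$geometry, g)$values
      fps[[i]] <- fp
      newly <- fp & claim == 0L
      claim[newly] <- i
    }
    # per-cell slope per sub-period, from the claiming reserve
    cell_slope <- lapply(seq_len(n_per), function(p) {
      m <- matrix(0, g$n_rows, g$n_cols)
      claimed <- claim > 0L
      m[claimed] <- slopes[claim[claimed], p]
      m
    })
    years <- cfg$years
    delta <- matrix(0, g$n_rows, g$n_cols)
    layers <- vector("list", length(years))
    prev_year <- years[1L]
    period_of <- function(y) {
      for (p in seq_len(n_per))
        if (y >= breaks[[p]][1L] && y <= breaks[[p]][2L]) return(p)
      n_per
    }
    for (k in seq_along(years)) {
      y <- years[k]
      if (k > 1L) {
        # advance by one year using the slope of the period the year lands in
        delta <- delta + cell_slope[[period_of(y)]] * (y - prev_year)
      }
      prev_year <- y
      q <- base + delta
      if (tr$noise_sd > 0)
        q <- q + matrix(stats::rnorm(length(q), sd = tr$noise_sd),
                        nrow(q), ncol(q))
      q <- pmin(pmax(q, 0), 1)
      layers[[k]] <- continuous_layer(g, q, name = paste0("quality_", y))
    }
    stack <- quality_stack(years, layers)
    # true per-reserve slopes: area-weighted mean of footprint cell slopes
    true_slopes <- do.call(rbind, lapply(seq_len(nrec), function(i) {
      idx <- which(fps[[i]] & g$land)
      row <- data.frame(id = records[[i]]$id, stringsAsFactors = FALSE)
      for (p in seq_len(n_per)) {
        s <- if (length(idx)) sum(cell_slope[[p]][idx] * w[idx]) / sum(w[idx])
             else NA_real_
        row[[sprintf("slope_%d_%d", breaks[[p]][1L], breaks[[p]][2L])]] <- s
      }
      row
    }))
    list(stack = stack, true_slopes = true_slopes)
  })
}

#' Generate a smooth pressure surface
#'
#' Autocorrelated noise min-max scaled to `cfg$pressure_range`
#' (default 0-50, Human-Footprint-like).
#'
#' @param cfg a [world_config].
#' @param world output of [gen_world].
#' @return a `continuous_layer` named "pressure".
#' @export
gen_pressure <- function(cfg, world) {
  g <- world$grid
  with_substream(cfg$seed, 8L, {
    m <- smooth_noise(g$n_rows, g$n_cols, autocorr = 8)
    land_v <- m[g$land]
    m <- (m - min(land_v)) / max(max(land_v) - min(land_v), 1e-12)
    m <- cfg$pressure_range[1L] +
      m * (cfg$pressure_range[2L] - cfg$pressure_range[1L])
    continuous_layer(g, m, name = "pressure")
  })
}

#' Generate a complete synthetic world with ground-truth bookkeeping
#'
#' Runs all the generators off one root seed (fixed substreams per
#' component) and records a `truth` list — realized template shares,
#' per-network masks and achieved overlaps, per-reserve rasterized
#' areas and designation years, per-stratum coverage percents counted
#' directly from the layers, and true trend slopes — against which every
#' downstream module can be checked.
#'
#' @param cfg a [world_config].
#' @return list with `cfg`, `grid`, `land`, `provinces`, `regions`,
#'   `biomes`, `templates`, `records`, `quality`, `pressure`, `truth`.
#' @export
gen_synthetic_world <- function(cfg = world_config()) {
  world <- gen_world(cfg)
  tpl <- gen_templates(cfg, world)
  res <- gen_reserves(cfg, world)
  qs <- gen_quality_stack(cfg, world, res$records)
  pressure <- gen_pressure(cfg, world)

  g <- world$grid
  w <- cell_areas(g)
  nm <- res$truth$network_masks
  pa_oecm_v <- nm$PA$values | nm$OECM$values
  with_br_v <- pa_oecm_v | nm$BR$values
  land_v <- g$land
  pct <- function(num_v, den_v) 100 * sum(w[num_v & den_v]) / sum(w[den_v])
  strat_truth <- function(zones) {
    t(vapply(zones$zone_table$zone_id, function(zid) {
      zv <- !is.na(zones$zone_id) & zones$zone_id == zid
      c(pct_without = pct(pa_oecm_v, zv), pct_with = pct(with_br_v, zv))
    }, c(pct_without = 0, pct_with = 0)))
  }
  nets <- names(nm)
  overlap <- matrix(0, length(nets), length(nets),
                    dimnames = list(nets, nets))
  for (a in nets) for (b in nets)
    overlap[a, b] <- sum(w[nm[[a]]$values & nm[[b]]$values])

  truth <- list(
    template_shares = tpl$realized_shares,
    reserves = res$truth$reserves,
    network_masks = nm,
    achieved_overlap = res$truth$achieved_overlap,
    network_overlap_km2 = overlap,
    coverage = list(
      global = c(pct_without = pct(pa_oecm_v, land_v),
                 pct_with = pct(with_br_v, land_v)),
      province = strat_truth(world$provinces),
      region = strat_truth(world$regions),
      biome = strat_truth(world$biomes)),
    true_slopes = qs$true_slopes)

  list(cfg = cfg, grid = g, land = world$land,
       provinces = world$provinces, regions = world$regions,
       biomes = world$biomes, templates = tpl$templates,
       records = res$records, quality = qs$stack, pressure = pressure,
       truth = truth)
}
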