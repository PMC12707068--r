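#' Binary opportunity template
#'
#' One of the global binary masks marking land relevant to an area-based
#' conservation target (the canonical six: Biodiversity Hotspots "BH",
#' Risk Ecoregions "RE", Phylogenetic Diversity hotspots "PD", Traded
#' Functional Diversity hotspots "TF", High Biomass Carbon "BC",
#' Indigenous Lands "IL"). Carries its global land-area share `p`, the
#' input to the rarity weighting.
#'
#' @param mask a terrestrial `binary_layer`.
#' @param name template label.
#' @return An object of class `template_layer` with fields `name`,
#'   `mask`, `p` and an `unweightable` flag when `p = 0`.
#' @export
template_layer <- function(mask, name = mask$name) {
  stopifnot(inherits(mask, "binary_layer"))
  p <- template_share_impl(mask)
  structure(list(name = name, mask = mask, p = p, unweightable = p == 0),
            class = "template_layer")
}

template_share_impl <- function(mask) {
  land <- mask_area(land_mask(mask$grid))
  if (land <= 0) stop("grid has no land area")
  mask_area(mask) / land
}

#' Global land-area share of a template
#' @param t a `template_layer`.
#' @return share in [0, 1]; 0 flags the template as unweightable.
#' @export
template_share <- function(t) {
  stopifnot(inherits(t, "template_layer"))
  t$p
}

#' Ordered set of templates on one grid
#' @param ... `template_layer` objects, or one list of them.
#' @return An object of class `template_set`.
#' @export
template_set <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && !inherits(ts[[1L]], "template_layer"))
    ts <- ts[[1L]]
  stopifnot(length(ts) >= 1L,
            all(vapply(ts, inherits, TRUE, "template_layer")))
  nms <- vapply(ts, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("template names must be unique")
  g <- ts[[1L]]$mask$grid
  for (t in ts[-1L])
    if (!same_grid(g, t$mask$grid)) stop("templates on different grids")
  names(ts) <- nms
  structure(list(templates = ts, n = length(ts)), class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("template_set: %d templates (%s); shares %s\n", x$n,
              paste(names(x$templates), collapse = ", "),
              paste(sprintf("%.3f", vapply(x$templates, `[[`, 0, "p")),
                    collapse = ", ")))
  invisible(x)
}

#' Top-decile intersection hotspot template
#'
#' Reproduces the hotspot-derivation recipe used for phylogenetic- and
#' functional-diversity templates: within each continuous layer, select
#' the top `q` fraction of land area (cells at or above the
#' area-weighted `1 - q` quantile; boundary ties are included, so the
#' realized share can exceed `q`), then intersect the selections across
#' layers.
#'
#' @param layers list of `continuous_layer` on one grid (e.g. one per
#'   taxon).
#' @param q top fraction to keep per layer (default 0.10).
#' @param name label for the resulting template.
#' @return A `template_layer`.
#' @export
top_decile_intersection <- function(layers, q = 0.10, name = "hotspot") {
  if (inherits(layers, "continuous_layer")) layers <- list(layers)
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "continuous_layer")),
            q > 0, q < 1)
  g <- layers[[1L]]$grid
  for (l in layers[-1L])
    if (!same_grid(g, l$grid)) stop("layers on different grids")
  w <- cell_areas(g)
  sel <- matrix(TRUE, g$n_rows, g$n_cols)
  for (l in layers) {
    idx <- which(!is.na(l$values))
    if (!length(idx)) stop("layer '", l$name, "' has no valid cells")
    v <- l$values[idx]
    o <- order(v, decreasing = TRUE)
    cum <- cumsum(w[idx][o])
    target <- q * sum(w[g$land])
    k <- which(cum >= target)[1L]
    if (is.na(k)) k <- length(o)
    thr <- v[o][k]
    m <- matrix(FALSE, g$n_rows, g$n_cols)
    m[idx] <- l$values[idx] >= thr
    sel <- sel & m
  }
  template_layer(binary_layer(g, sel, name = name), name = name)
}

#' Representativeness of a template under three network definitions
#'
#' Percent of the template's area falling inside (i) the BR network,
#' (ii) the PA/OECM network, and (iii) their union, together with the
#' random-placement baseline: the BR network's own share of land,
#' which is what a spatially random sample of equal area would capture
#' in expectation.
#'
#' @param t a `template_layer`.
#' @param br,pa_oecm `binary_layer` network masks on the template's grid.
#' @return one-row data.frame: `template`, `pct_BR`, `pct_PA_OECM`,
#'   `pct_combined`, `baseline_pct`, `defined`.
#' @export
representativeness <- function(t, br, pa_oecm) {
  stopifnot(inherits(t, "template_layer"),
            inherits(br, "binary_layer"), inherits(pa_oecm, "binary_layer"))
  g <- t$mask$grid
  if (!same_grid(g, br$grid) || !same_grid(g, pa_oecm$grid))
    stop("representativeness: layers on different grids")
  ta <- mask_area(t$mask)
  baseline <- 100 * mask_area(br) / mask_area(land_mask(g))
  if (ta <= 0)
    return(data.frame(template = t$name, pct_BR = NA_real_,
                      pct_PA_OECM = NA_real_, pct_combined = NA_real_,
                      baseline_pct = baseline, defined = FALSE,
                      stringsAsFactors = FALSE))
  comb <- union_masks(br, pa_oecm)
  data.frame(template = t$name,
             pct_BR = 100 * mask_area(t$mask, within = br) / ta,
             pct_PA_OECM = 100 * mask_area(t$mask, within = pa_oecm) / ta,
             pct_combined = 100 * mask_area(t$mask, within = comb) / ta,
             baseline_pct = baseline, defined = TRUE,
             stringsAsFactors = FALSE)
}

#' Representativeness report for a whole template set
#'
#' @inheritParams representativeness
#' @param ts a `template_set`.
#' @param zones optional `zone_partition`; when given, per-zone rows are
#'   appended (template area restricted to the zone; zones with no
#'   template area yield undefined rows).
#' @return data.frame of class `representativeness_report`.
#' @export
representativeness_report <- function(ts, br, pa_oecm, zones = NULL) {
  stopifnot(inherits(ts, "template_set"))
  glob <- do.call(rbind, lapply(ts$templates, representativeness,
                                br = br, pa_oecm = pa_oecm))
  glob$zone <- "global"
  out <- glob
  if (!is.null(zones)) {
    g <- br$grid
    for (i in seq_len(nrow(zones$zone_table))) {
      zid <- zones$zone_table$zone_id[i]
      zmask <- binary_layer(g, !is.na(zones$zone_id) & zones$zone_id == zid,
                            name = zones$zone_table$name[i])
      for (t in ts$templates) {
        tz <- template_layer(intersect_masks(t$mask, zmask), name = t$name)
        row <- representativeness(tz, br, pa_oecm)
        row$zone <- zones$zone_table$name[i]
        out <- rbind(out, row)
      }
    }
  }
  rownames(out) <- NULL
  class(out) <- c("representativeness_report", "data.frame")
  out
}

#' Overlay multiplicity: how many templates cover each cell
#'
#' Counts, per land cell, the number of templates containing it (0 to
#' n), tabulates land area by count, and, for each template, the
#' fraction of its area overlapping exactly k of the other templates.
#'
#' @param ts a `template_set`.
#' @return list with `counts` (`continuous_layer` of integers),
#'   `histogram` (data.frame `count`, `area_km2`, `pct_land`) and
#'   `composition` (matrix template x k, k = 0..n-1, rows summing to 1).
#' @export
overlay_multiplicity <- function(ts) {
  stopifnot(inherits(ts, "template_set"))
  g <- ts$templates[[1L]]$mask$grid
  cnt <- Reduce(`+`, lapply(ts$templates, function(t) t$mask$values * 1L))
  w <- cell_areas(g)
  land_idx <- which(g$land)
  land_area <- sum(w[land_idx])
  histogram <- data.frame(count = 0:ts$n, area_km2 = 0, pct_land = 0)
  for (k in 0:ts$n) {
    a <- sum(w[land_idx][cnt[land_idx] == k])
    histogram$area_km2[k + 1L] <- a
    histogram$pct_land[k + 1L] <- 100 * a / land_area
  }
  comp <- matrix(NA_real_, ts$n, ts$n,
                 dimnames = list(names(ts$templates),
                                 paste0("k", 0:(ts$n - 1L))))
  for (i in seq_len(ts$n)) {
    m <- ts$templates[[i]]$mask$values
    idx <- which(m)
    ta <- sum(w[idx])
    if (ta <= 0) next
    others <- cnt[idx] - 1L  # overlaps with the other n-1 templates
    for (k in 0:(ts$n - 1L))
      comp[i, k + 1L] <- sum(w[idx][others == k]) / ta
  }
  counts_layer <- continuous_layer(g, cnt * 1.0, name = "overlay_count")
  list(counts = counts_layer, histogram = histogram, composition = comp)
}
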