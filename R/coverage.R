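#' Coverage report: conserved-area percent with and without BRs
#'
#' For each stratum (or globally when `zones` is NULL) computes the
#' percent of terrestrial stratum area covered by the PA/OECM network,
#' the percent covered once biosphere reserves are unioned in, the
#' uplift in percentage points, and flags against the 17% (Aichi) and
#' 30% (KMGBF Target 3) area thresholds. Denominators are always the
#' stratum's terrestrial area; threshold comparisons use `>=` so an
#' exact tie counts as met.
#'
#' @param pa_oecm `binary_layer`: union of the PA and OECM networks.
#' @param br `binary_layer`: the biosphere-reserve network.
#' @param zones optional `zone_partition` defining the strata.
#' @param stratum_kind label recorded on the report ("global", "region",
#'   "ecosystem", "country", "province").
#' @param thresholds two percents to flag against (default c(17, 30)).
#' @return data.frame of class `coverage_report` with columns `stratum`,
#'   `pct_without`, `pct_with`, `uplift_pts`, `meets17_without`,
#'   `meets17_with`, `meets30_without`, `meets30_with`, `defined`.
#' @examples
#' g <- grid_spec(10, 10)
#' pa <- binary_layer(g, matrix(seq_len(100) <= 20, 10, 10))
#' br <- binary_layer(g, matrix(seq_len(100) > 95, 10, 10))
#' coverage_report(pa, br)  # 20% -> 25%
#' @export
coverage_report <- function(pa_oecm, br, zones = NULL,
                            stratum_kind = if (is.null(zones)) "global" else "zone",
                            thresholds = c(17, 30)) {
  stopifnot(inherits(pa_oecm, "binary_layer"), inherits(br, "binary_layer"))
  if (!same_grid(pa_oecm$grid, br$grid))
    stop("coverage_report: layers on different grids")
  combined <- union_masks(pa_oecm, br, name = "pa_oecm | br")
  if (is.null(zones)) {
    land <- land_mask(pa_oecm$grid)
    denom <- mask_area(land)
    out <- data.frame(stratum = "global",
                      pct_without = 100 * mask_area(pa_oecm) / denom,
                      pct_with = 100 * mask_area(combined) / denom,
                      defined = denom > 0, stringsAsFactors = FALSE)
  } else {
    if (!same_grid(pa_oecm$grid, zones$grid))
      stop("coverage_report: zones on a different grid")
    without <- zonal_fraction(pa_oecm, zones)
    with <- zonal_fraction(combined, zones)
    out <- data.frame(stratum = without$name,
                      pct_without = without$percent,
                      pct_with = with$percent,
                      defined = without$defined, stringsAsFactors = FALSE)
  }
  out$uplift_pts <- out$pct_with - out$pct_without
  f <- function(p, thr) !is.na(p) & p >= thr
  out$meets17_without <- f(out$pct_without, thresholds[1L])
  out$meets17_with <- f(out$pct_with, thresholds[1L])
  out$meets30_without <- f(out$pct_without, thresholds[2L])
  out$meets30_with <- f(out$pct_with, thresholds[2L])
  out <- out[, c("stratum", "pct_without", "pct_with", "uplift_pts",
                 "meets17_without", "meets17_with",
                 "meets30_without", "meets30_with", "defined")]
  attr(out, "stratum_kind") <- stratum_kind
  attr(out, "thresholds") <- thresholds
  class(out) <- c("coverage_report", "data.frame")
  out
}

#' Uplift (percentage points) per stratum from a coverage report
#' @param report a `coverage_report`.
#' @return data.frame with `stratum` and `uplift_pts` (never negative).
#' @export
coverage_uplift <- function(report) {
  stopifnot(inherits(report, "coverage_report"))
  data.frame(stratum = report$stratum, uplift_pts = report$uplift_pts,
             stringsAsFactors = FALSE)
}

#' Flags against the 17% and 30% area-based targets
#' @param percent coverage percent(s) on the 0-100 scale.
#' @return for one value, named logical `c(meets_17, meets_30)`; for a
#'   vector, a two-column logical matrix.
#' @export
threshold_flags <- function(percent) {
  if (any(is.na(percent)) || any(percent < 0 | percent > 100))
    stop("percent must lie in [0, 100]")
  out <- cbind(meets_17 = percent >= 17, meets_30 = percent >= 30)
  if (length(percent) == 1L) out[1L, ] else out
}
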