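#' Annual habitat-quality stack
#'
#' One continuous [0, 1] quality layer per year on a shared grid. Quality
#' summarizes the capacity of habitat to support species (0 = lowest,
#' 1 = highest); the stack is consumed as input, never recomputed here.
#'
#' @param years strictly increasing integer years.
#' @param layers list of `continuous_layer`, one per year, on one grid.
#' @return An object of class `quality_stack`.
#' @export
quality_stack <- function(years, layers) {
  years <- as.integer(years)
  stopifnot(length(years) == length(layers), length(years) >= 1L,
            all(diff(years) > 0),
            all(vapply(layers, inherits, TRUE, "continuous_layer")))
  g <- layers[[1L]]$grid
  for (l in layers[-1L])
    if (!same_grid(g, l$grid)) stop("stack layers on different grids")
  for (l in layers) {
    v <- l$values[!is.na(l$values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("quality values must lie in [0, 1]")
  }
  structure(list(years = years, layers = stats::setNames(layers, years),
                 grid = g), class = "quality_stack")
}

#' @export
print.quality_stack <- function(x, ...) {
  cat(sprintf("quality_stack: %d years (%d-%d)\n", length(x$years),
              min(x$years), max(x$years)))
  invisible(x)
}

#' Designation-aligned quality series for one reserve
#'
#' Extracts the per-year area-weighted mean quality over the reserve's
#' footprint, starting five years before designation (to capture
#' pre-designation preparatory management) but never before the stack's
#' first year — so a reserve designated in or before
#' `first stack year + 5` starts at the stack's first year.
#'
#' @param record `reserve_record` with resolved geometry.
#' @param stack a `quality_stack`.
#' @param lead_years years of pre-designation context (default 5).
#' @return An object of class `reserve_series`: `id`, `start_year`,
#'   `values` (named numeric, year to mean quality), `defined`.
#' @export
reserve_series <- function(record, stack, lead_years = 5L) {
  stopifnot(inherits(record, "reserve_record"),
            inherits(stack, "quality_stack"))
  if (is.null(record$geometry))
    stop("record geometry must be resolved first")
  start_year <- max(min(stack$years), record$designation_year - lead_years)
  fp <- rasterize_polygon(record$geometry, stack$grid, name = record$id)
  idx <- which(fp$values)
  w <- cell_areas(stack$grid)[idx]
  yrs <- stack$years[stack$years >= start_year]
  vals <- stats::setNames(rep(NA_real_, length(yrs)), yrs)
  defined <- FALSE
  if (length(idx)) {
    for (y in yrs) {
      v <- stack$layers[[as.character(y)]]$values[idx]
      ok <- !is.na(v)
      if (any(ok)) {
        vals[as.character(y)] <- sum(v[ok] * w[ok]) / sum(w[ok])
        defined <- TRUE
      }
    }
  }
  if (!defined)
    warning("reserve ", record$id, " has no quality cells; series undefined")
  structure(list(id = record$id, start_year = start_year, values = vals,
                 defined = defined), class = "reserve_series")
}

#' Aggregate reserve series by stratum
#'
#' Unweighted mean across reserves with a value in each year (each
#' reserve counts once, regardless of area; an area-weighted variant is
#' available). Per-year reserve counts are reported.
#'
#' @param series list of `reserve_series`.
#' @param strata named character: reserve id to stratum label; missing
#'   ids fall into "all".
#' @param weights optional named numeric (id to weight, e.g. area) for
#'   a weighted mean.
#' @return data.frame: `stratum`, `year`, `mean`, `n`.
#' @export
aggregate_series <- function(series, strata = NULL, weights = NULL) {
  stopifnot(all(vapply(series, inherits, TRUE, "reserve_series")))
  rows <- do.call(rbind, lapply(series, function(s) {
    if (!s$defined) return(NULL)
    data.frame(id = s$id, year = as.integer(names(s$values)),
               value = as.numeric(s$values), stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) return(data.frame(stratum = character(),
                                       year = integer(), mean = numeric(),
                                       n = integer()))
  rows <- rows[!is.na(rows$value), ]
  rows$stratum <- if (is.null(strata)) "all" else {
    s <- strata[rows$id]; s[is.na(s)] <- "all"; s
  }
  rows$w <- if (is.null(weights)) 1 else {
    w <- weights[rows$id]; w[is.na(w)] <- 0; w
  }
  agg <- do.call(rbind, lapply(split(rows, list(rows$stratum, rows$year),
                                     drop = TRUE), function(d) {
    data.frame(stratum = d$stratum[1L], year = d$year[1L],
               mean = sum(d$value * d$w) / sum(d$w), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$stratum, agg$year), ]
  rownames(agg) <- NULL
  agg
}

#' Default sub-period boundaries for piecewise trend fits
#' @return list of (lo, hi) year pairs: 1992-2000, 2001-2010, 2011-2020.
#' @export
default_breaks <- function() list(c(1992, 2000), c(2001, 2010), c(2011, 2020))

#' Piecewise sub-period trend regression
#'
#' Fits a separate ordinary-least-squares regression of quality on year
#' within each sub-period, reporting the slope (quality units per
#' year), its two-sided t-test p-value, the 95% confidence interval and
#' a significance label. Sub-periods with fewer than 3 observations are
#' skipped and flagged.
#'
#' @param series named numeric vector: year to value (names are years).
#' @param breaks list of `c(lo, hi)` year pairs; default
#'   [default_breaks()].
#' @return data.frame of class `trend_fit`: `period_lo`, `period_hi`,
#'   `n`, `slope`, `se`, `p_value`, `ci_lo`, `ci_hi`, `stars`,
#'   `skipped`.
#' @examples
#' yrs <- 1992:2020
#' piecewise_trend(stats::setNames(0.8 - 0.001 * (yrs - 1992), yrs))
#' @export
piecewise_trend <- function(series, breaks = default_breaks()) {
  years <- as.integer(names(series))
  if (anyNA(years)) stop("series must be named by year")
  out <- do.call(rbind, lapply(breaks, function(b) {
    sel <- years >= b[1L] & years <= b[2L] & !is.na(series)
    row <- data.frame(period_lo = b[1L], period_hi = b[2L], n = sum(sel),
                      slope = NA_real_, se = NA_real_, p_value = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_, stars = NA_character_,
                      skipped = TRUE, stringsAsFactors = FALSE)
    if (sum(sel) >= 3L) {
      d <- data.frame(year = years[sel], value = as.numeric(series[sel]))
      fit <- stats::lm(value ~ year, data = d)
      cf <- summary(fit)$coefficients
      ci <- stats::confint(fit, "year", level = 0.95)
      row$slope <- cf["year", "Estimate"]
      row$se <- cf["year", "Std. Error"]
      row$p_value <- cf["year", "Pr(>|t|)"]
      row$ci_lo <- ci[1L]; row$ci_hi <- ci[2L]
      row$stars <- significance_label(row$p_value)
      row$skipped <- FALSE
    }
    row
  }))
  class(out) <- c("trend_fit", "data.frame")
  out
}

#' Significance stars for slope p-values
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise.
#'
#' @param p p-value(s) in [0, 1].
#' @return character vector of labels.
#' @export
significance_label <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
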