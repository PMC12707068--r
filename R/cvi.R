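#' Rarity-based normalized template weights
#'
#' Each template i with global land-area share p_i receives weight
#' `w_i = (1/p_i) / sum_j (1/p_j)`, so rarer templates weigh more and
#' the weights sum to one exactly. A zero share leaves the weight
#' undefined; by default that aborts with the offending template named,
#' or, under `zero_share_policy = "drop"`, the template is excluded and
#' the remaining weights renormalized (logged via a warning).
#'
#' @param ts a `template_set`, or a numeric vector of shares in (0, 1].
#' @param zero_share_policy "error" (default) or "drop".
#' @return named numeric vector of class `weight_vector` summing to 1;
#'   attribute `p` carries the shares used.
#' @examples
#' rarity_weights(c(BH = 1/6, RE = 1/6, PD = 1/6, TF = 1/6,
#'                  BC = 1/6, IL = 1/6))
#' @export
rarity_weights <- function(ts, zero_share_policy = c("error", "drop")) {
  zero_share_policy <- match.arg(zero_share_policy)
  if (inherits(ts, "template_set")) {
    p <- vapply(ts$templates, `[[`, 0, "p")
  } else {
    p <- ts
    if (is.null(names(p))) names(p) <- paste0("t", seq_along(p))
  }
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("template shares must lie in [0, 1]")
  zero <- p == 0
  if (any(zero)) {
    if (zero_share_policy == "error")
      stop("template share is zero (weight undefined) for: ",
           paste(names(p)[zero], collapse = ", "))
    warning("dropping zero-share template(s): ",
            paste(names(p)[zero], collapse = ", "))
    p <- p[!zero]
    if (!length(p)) stop("all templates have zero share")
  }
  w <- (1 / p) / sum(1 / p)
  structure(w, p = p, class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("rarity weights (sum", format(sum(x), digits = 15), "):\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Rarity-weighted Conservation Value Index surface
#'
#' Per land cell, `CVI = sum_i w_i R_i` with `R_i` the cell's binary
#' membership in template i. Because the weights sum to one, CVI lies in
#' [0, 1], reaching 1 only where a cell hits every template.
#'
#' @param ts a `template_set`.
#' @param w a `weight_vector` from [rarity_weights] matching `ts` by
#'   name (templates dropped for zero share are simply absent).
#' @return a `continuous_layer` named "CVI".
#' @export
cvi_surface <- function(ts, w = rarity_weights(ts)) {
  stopifnot(inherits(ts, "template_set"))
  nm <- names(w)
  if (!all(nm %in% names(ts$templates)))
    stop("weight names do not match the template set")
  g <- ts$templates[[1L]]$mask$grid
  acc <- matrix(0, g$n_rows, g$n_cols)
  for (n in nm)
    acc <- acc + as.numeric(w[n]) * ts$templates[[n]]$mask$values
  continuous_layer(g, acc, name = "CVI")
}

#' Min-max standardization over land cells
#'
#' `(x - min) / (max - min)` across all valid terrestrial cells, mapping
#' the layer onto [0, 1] with the minimum at 0 and the maximum at 1. A
#' constant layer is degenerate: all values map to 0 and the result
#' carries a `degenerate` attribute (with a warning) so downstream
#' binning still runs.
#'
#' @param raw a `continuous_layer` with at least one valid cell.
#' @return a `continuous_layer`; attribute `degenerate` is TRUE when
#'   max equals min.
#' @export
minmax_standardize <- function(raw) {
  stopifnot(inherits(raw, "continuous_layer"))
  v <- raw$values
  ok <- !is.na(v)
  if (!any(ok)) stop("minmax_standardize: no valid cells")
  lo <- min(v[ok]); hi <- max(v[ok])
  out <- v
  degenerate <- hi == lo
  if (degenerate) {
    warning("degenerate standardization: max equals min; all values set to 0")
    out[ok] <- 0
  } else {
    out[ok] <- (v[ok] - lo) / (hi - lo)
  }
  res <- continuous_layer(raw$grid, out, name = paste0(raw$name, "_std"))
  attr(res, "degenerate") <- degenerate
  res
}

#' Province-level coverage, conservation value and pressure
#'
#' Summarizes, per zone of the partition, the percent covered by the
#' combined conservation network, the area-weighted mean (or median) of
#' the standardized CVI, and optionally the zonal mean of a pressure
#' surface (Human-Footprint style).
#'
#' @param cvi_std standardized CVI `continuous_layer`.
#' @param network `binary_layer`: union of BR, PA and OECM masks.
#' @param zones `zone_partition` (e.g. biogeographical provinces).
#' @param pressure optional `continuous_layer`.
#' @param value_aggregation "mean" (default) or "median".
#' @return data.frame of class `province_summary`: `zone_id`, `name`,
#'   `coverage_pct`, `value`, `mean_pressure`, `defined`.
#' @export
province_summaries <- function(cvi_std, network, zones, pressure = NULL,
                               value_aggregation = c("mean", "median")) {
  value_aggregation <- match.arg(value_aggregation)
  stopifnot(inherits(cvi_std, "continuous_layer"),
            inherits(network, "binary_layer"),
            inherits(zones, "zone_partition"))
  cov <- zonal_fraction(network, zones)
  if (value_aggregation == "mean") {
    val <- zonal_mean(cvi_std, zones)
    value <- val$mean
  } else {
    value <- rep(NA_real_, nrow(zones$zone_table))
    cells <- zone_cells(zones)
    for (i in seq_along(value)) {
      idx <- cells[[as.character(zones$zone_table$zone_id[i])]]
      if (!is.null(idx)) {
        v <- cvi_std$values[idx]
        if (any(!is.na(v))) value[i] <- stats::median(v, na.rm = TRUE)
      }
    }
  }
  out <- data.frame(zone_id = cov$zone_id, name = cov$name,
                    coverage_pct = cov$percent, value = value,
                    mean_pressure = NA_real_,
                    defined = cov$defined & !is.na(value),
                    stringsAsFactors = FALSE)
  if (!is.null(pressure)) {
    pm <- zonal_mean(pressure, zones)
    out$mean_pressure <- pm$mean
  }
  class(out) <- c("province_summary", "data.frame")
  out
}

#' Empirical sextile bins (Q1 lowest ... Q6 highest)
#'
#' Ranks the values ascending and assigns rank r of N to bin
#' `ceiling(6 r / N)`. Ties are broken by stable id order
#' (lexicographic) so the binning is deterministic; a warning notes when
#' ties were broken this way.
#'
#' @param values named numeric vector (names are the ids); NAs dropped.
#' @param n_bins number of quantile bins (default 6).
#' @return named character vector of bins "Q1".."Q6" for the defined
#'   ids, in input order.
#' @export
sextile_bins <- function(values, n_bins = 6L) {
  if (is.null(names(values))) names(values) <- as.character(seq_along(values))
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < n_bins)
    stop("sextile_bins needs at least ", n_bins, " defined values, got ", n)
  if (anyDuplicated(values))
    warning("ties in values broken by stable id order")
  o <- order(values, names(values), method = "radix")
  rank <- integer(n)
  rank[o] <- seq_len(n)
  bins <- paste0("Q", ceiling(n_bins * rank / n))
  names(bins) <- names(values)
  bins
}

#' Select expansion-priority provinces from the 6 x 6 matrix
#'
#' Bins provinces independently into sextiles of conservation value and
#' of coverage, then flags as priorities those combining high value
#' (Q5-Q6) with low coverage (Q1-Q2) — ecologically significant but
#' under-protected zones.
#'
#' @param summary a `province_summary` (from [province_summaries]) with
#'   at least 6 defined rows.
#' @return data.frame of class `priority_matrix`: the summary columns
#'   plus `coverage_bin`, `value_bin`, `priority`.
#' @export
select_priorities <- function(summary) {
  stopifnot(inherits(summary, "province_summary") || is.data.frame(summary))
  ok <- summary$defined & !is.na(summary$coverage_pct) & !is.na(summary$value)
  if (sum(ok) < 6L) stop("need at least 6 defined provinces to bin")
  ids <- as.character(summary$zone_id[ok])
  cov_bin <- sextile_bins(stats::setNames(summary$coverage_pct[ok], ids))
  val_bin <- sextile_bins(stats::setNames(summary$value[ok], ids))
  out <- summary
  out$coverage_bin <- NA_character_
  out$value_bin <- NA_character_
  out$coverage_bin[ok] <- cov_bin[ids]
  out$value_bin[ok] <- val_bin[ids]
  out$priority <- !is.na(out$value_bin) &
    out$value_bin %in% c("Q5", "Q6") &
    out$coverage_bin %in% c("Q1", "Q2")
  class(out) <- c("priority_matrix", "data.frame")
  out
}
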