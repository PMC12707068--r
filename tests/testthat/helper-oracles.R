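# Independent brute-force oracles used across the suite. These never call
# the code paths they check.

# product-form evaluation of the rarity weights: w_i = prod_{j!=i} p_j
# normalized -- algebraically equal to (1/p_i)/sum(1/p_j) but computed
# through a different arithmetic path
oracle_rarity_weights <- function(p) {
  numer <- vapply(seq_along(p), function(i) prod(p[-i]), 0)
  numer / sum(numer)
}

# per-cell scan: count of cells whose center lies inside a circle
oracle_disc_cell_count <- function(grid, center, radius) {
  cc <- cell_centers(grid)
  n <- 0L
  for (r in seq_len(grid$n_rows))
    for (c in seq_len(grid$n_cols))
      if ((cc$x[c] - center[1])^2 + (cc$y[r] - center[2])^2 <= radius^2)
        n <- n + 1L
  n
}

# brute-force area of a mask restricted to a zone, by cell scan
oracle_masked_area <- function(values, w, sel) sum(w[values & sel])

# brute-force sextile binning: sort by (value, id), walk ranks
oracle_sextiles <- function(values, n_bins = 6L) {
  ids <- names(values)
  o <- order(values, ids, method = "radix")
  bins <- character(length(values))
  for (k in seq_along(o))
    bins[o[k]] <- paste0("Q", ceiling(n_bins * k / length(o)))
  names(bins) <- ids
  bins
}

# small all-land world with a deterministic checkerboard-ish template set
toy_grid <- function(n = 10L) grid_spec(n, n)

rand_mask <- function(grid, p = 0.3) {
  binary_layer(grid,
               matrix(stats::runif(grid$n_rows * grid$n_cols) < p,
                      grid$n_rows, grid$n_cols))
}

# fast small synthetic world for cross-module tests
small_world_cfg <- function(seed, n = 60L, ...) {
  world_config(n_rows = n, n_cols = n, n_provinces = 8L, seed = seed, ...)
}
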