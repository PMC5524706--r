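# Shared fixtures, all built in code at test time.

# Homogeneous fully suitable landscape, flat latitude (French-baseline).
flat_grid <- function(extent_km = 400, cell_km = 4, lat_deg = 44.74) {
  n <- extent_km / cell_km
  landscape_grid(matrix(2L, n, n), cell_km = cell_km,
                 lat_at_origin_deg = lat_deg, km_per_degree_lat = Inf)
}

# All-water landscape (nothing settleable).
water_grid <- function(n = 10, cell_km = 1) {
  g <- landscape_grid(matrix(2L, n, n), cell_km = cell_km)
  g$classes[] <- 5L
  g
}

# Left half urban (weight 1), right half woodland (weight 0.5).
split_grid <- function(extent_km = 800, cell_km = 4) {
  n <- extent_km / cell_km
  cl <- matrix(3L, n, n)
  cl[, seq_len(n / 2)] <- 1L
  landscape_grid(cl, cell_km = cell_km, km_per_degree_lat = Inf)
}

# Small heterogeneous landscape with a latitude gradient, for risk-map
# cross-checks.
patchy_grid <- function(seed = 5, n = 60, cell_km = 2) {
  generate_landscape(n, n, cell_km = cell_km,
                     proportions = c(urban = 0.1, agricultural = 0.5,
                                     woodland = 0.15, water = 0.1),
                     patch_km = 8, coast = FALSE, seed = seed,
                     lat_at_origin_deg = 51, km_per_degree_lat = 111)
}

# Text of a tiny ESRI ASCII grid.
tiny_asc_text <- function(nodata = -9999) {
  c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
    "cellsize 1", paste("NODATA_value", nodata),
    "1 2",   # northern row
    "3 4")   # southern row
}

single_nest <- function(x, y) {
  data.frame(id = 1L, x_km = x, y_km = y, year_founded = 1L,
             parent_id = NA_integer_, status = "active")
}
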