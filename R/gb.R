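# A reference synthetic landscape emulating the south-west of Great
# Britain, used by the worked examples and the desk-scale risk-map
# analyses. It is a stand-in built with generate_landscape(), not real
# geography: a 400 x 440 km coastal region with water along the south and
# west (Bristol Channel / Severn side), a linear latitude frame starting
# at 50 degN on the southern edge, and urban/agricultural/woodland cover
# in realistic proportions. Its construction seed is fixed so that all
# analyses share one landscape.

GB_LANDSCAPE_SEED <- 20160920L

#' Synthetic GB-like coastal landscape
#'
#' A fixed synthetic landscape emulating south-western Great Britain:
#' 400 km (east-west) by 440 km (north-south), water margin along the
#' south and west edges, latitude 50 degN at the southern edge rising
#' linearly northward (111 km per degree). The same landscape (up to cell
#' size) is returned on every call; it stands in for real land-cover
#' rasters so every analysis runs without external data.
#'
#' @param cell_km cell size in km (default 2; use 8 for the cheaper
#'   extinction fixed-point solves).
#' @return a [landscape_grid()].
#' @export
#' @examples
#' gb_landscape(cell_km = 8)
gb_landscape <- function(cell_km = 2) {
  generate_landscape(n_rows = round(440 / cell_km),
                     n_cols = round(400 / cell_km),
                     cell_km = cell_km,
                     proportions = c(urban = 0.06, agricultural = 0.45,
                                     woodland = 0.10, water = 0.30),
                     patch_km = 12, coast = TRUE,
                     seed = GB_LANDSCAPE_SEED,
                     lat_at_origin_deg = 50, km_per_degree_lat = 111)
}

#' The two 2016 sightings on the synthetic landscape
#'
#' Coordinates mimicking the first confirmed records: a nest near Tetbury,
#' Gloucestershire (51.64 degN) and a single worker hornet in North
#' Somerset about 40 km to the south-west, placed in the synthetic
#' landscape's coordinate frame. The hornet sighting is treated as
#' evidence of a nest at its location.
#'
#' @return data.frame with columns `x_km`, `y_km`, `year`, `type`.
#' @export
gb_sightings <- function() {
  data.frame(x_km = c(248, 214),
             y_km = c(182.04, 160),   # latitudes 51.64 and 51.44 degN
             year = c(2016L, 2016L),
             type = c("nest", "hornet"))
}
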