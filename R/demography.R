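# Demography module: expected number of successful daughter queens per nest.
#
# mu = scaling_sigma * R_A * latitude_scaling(lat) * g(crowding), zero on
# water. R_A is the mean number of daughter queens that survive hibernation
# and found a nest, for a low-density nest at the Andernos-les-Bains
# reference latitude; the latitude term is a linear cline reaching zero in
# northern England; g is density-dependent competition.

#' Demographic parameters
#'
#' @param R_A mean successful daughter queens per nest at the
#'   Andernos-les-Bains baseline, at low density. The default 8.7 is the
#'   baseline reproduction implied by an expected 3.3 daughters at 38% of
#'   baseline potential.
#' @param lat_A_deg latitude of the Andernos-les-Bains reference population.
#' @param lat_zero_deg latitude at which the reproduction cline reaches zero
#'   (northern England). The default 55.9 makes the cline pass through 38%
#'   at 51.64 degN.
#' @param K_half crowding count at which reproduction is halved.
#' @param r_c_km radius (km) of the local competition neighbourhood.
#' @param scaling_sigma global multiplier on reproductive potential
#'   (1 = the Andernos baseline).
#' @param dd_form density-dependence form: `"hyperbolic"` gives
#'   `g(n) = 1 / (1 + n / K_half)`, `"exponential"` gives
#'   `g(n) = exp(-n / K_half)`. Both are monotone and equal 1 at `n = 0`,
#'   so low-density quantities do not depend on the choice.
#' @return an object of class `demography_params`.
#' @export
#' @examples
#' demography_params()
demography_params <- function(R_A = 8.7, lat_A_deg = 44.74,
                              lat_zero_deg = 55.9, K_half = 50,
                              r_c_km = 5, scaling_sigma = 1,
                              dd_form = c("hyperbolic", "exponential")) {
  dd_form <- match.arg(dd_form)
  if (R_A <= 0) stop("R_A must be positive")
  if (lat_zero_deg <= lat_A_deg)
    stop("lat_zero_deg must lie north of lat_A_deg")
  if (K_half <= 0) stop("K_half must be positive")
  if (r_c_km <= 0) stop("r_c_km must be positive")
  if (scaling_sigma < 0) stop("scaling_sigma must be non-negative")
  structure(list(R_A = R_A, lat_A_deg = lat_A_deg, lat_zero_deg = lat_zero_deg,
                 K_half = K_half, r_c_km = r_c_km,
                 scaling_sigma = scaling_sigma, dd_form = dd_form),
            class = "demography_params")
}

#' @export
print.demography_params <- function(x, ...) {
  cat(sprintf(paste0("<demography_params> R_A %g queens/nest at %g degN, ",
                     "zero cline %g degN\n  K_half %g, r_c %g km, sigma %g, ",
                     "density dependence: %s\n"),
              x$R_A, x$lat_A_deg, x$lat_zero_deg, x$K_half, x$r_c_km,
              x$scaling_sigma, x$dd_form))
  invisible(x)
}

#' Linear latitude scaling of reproductive potential
#'
#' Fraction of the Andernos-les-Bains reproductive potential realised at a
#' given latitude: `clamp((lat_zero - lat) / (lat_zero - lat_A), 0, 1)`.
#' The clamp at 1 south of the reference latitude is a conservative choice
#' (no super-baseline reproduction); north of the zero cline reproduction
#' is zero.
#'
#' @param lat_deg latitude(s) in degrees north.
#' @param params a [demography_params()].
#' @return fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' latitude_scaling(51.64, demography_params())  # ~0.38 at Tetbury
latitude_scaling <- function(lat_deg, params = demography_params()) {
  if (is.infinite(params$lat_zero_deg)) return(rep(1, length(lat_deg)))
  f <- (params$lat_zero_deg - lat_deg) /
       (params$lat_zero_deg - params$lat_A_deg)
  pmin(pmax(f, 0), 1)
}

# Invert the cline: the lat_zero that realises fraction `ratio` at `lat_deg`
# while keeping the scaling equal to 1 at lat_A. Used by sensitivity sweeps.
lat_zero_for_ratio <- function(ratio, lat_deg, lat_A_deg = 44.74) {
  stopifnot(ratio >= 0, ratio < 1, lat_deg > lat_A_deg)
  (lat_deg - ratio * lat_A_deg) / (1 - ratio)
}

#' Count of competing nests within the competition radius
#'
#' Number of other active nests within Euclidean distance `r_c_km`
#' (boundary inclusive) of a focal location. The focal nest itself, when
#' present in `nests`, is identified by `exclude` (its row index) and not
#' counted.
#'
#' @param nests data.frame with columns `x_km`, `y_km` (and optionally
#'   `status`; destroyed nests are not counted).
#' @param x_km,y_km focal location.
#' @param r_c_km competition radius in km.
#' @param exclude optional row index of the focal nest in `nests`.
#' @return non-negative integer count.
#' @export
local_crowding <- function(nests, x_km, y_km, r_c_km, exclude = NULL) {
  if (r_c_km <= 0) stop("r_c_km must be positive")
  if (nrow(nests) == 0) return(0L)
  keep <- rep(TRUE, nrow(nests))
  if (!is.null(nests$status)) keep <- nests$status == "active"
  if (!is.null(exclude)) keep[exclude] <- FALSE
  d2 <- (nests$x_km - x_km)^2 + (nests$y_km - y_km)^2
  sum(keep & d2 <= r_c_km^2 + 1e-12)
}

# Density-dependent competition factor g(n).
dd_factor <- function(crowding, params) {
  switch(params$dd_form,
         hyperbolic = 1 / (1 + crowding / params$K_half),
         exponential = exp(-crowding / params$K_half))
}

#' Expected number of successful daughter queens
#'
#' The Poisson mean for a nest at `(x_km, y_km)` with `crowding` competing
#' nests: `scaling_sigma * R_A * latitude_scaling(lat) * g(crowding)`, and 0
#' if the nest's cell is water (or outside the grid). Habitat preference
#' among non-water classes acts at settlement, not reproduction, to avoid
#' double counting.
#'
#' @param x_km,y_km nest location(s); vectorised.
#' @param crowding competing-nest count(s), non-negative.
#' @param grid a [landscape_grid()].
#' @param params a [demography_params()].
#' @return non-negative Poisson mean(s).
#' @export
#' @examples
#' g <- landscape_grid(matrix(2L, 10, 10), cell_km = 10,
#'                     lat_at_origin_deg = 51.2)
#' expected_queens(50, 50, 0, g, demography_params())
expected_queens <- function(x_km, y_km, crowding, grid,
                            params = demography_params()) {
  if (any(crowding < 0)) stop("crowding must be non-negative")
  mu <- params$scaling_sigma * params$R_A *
    latitude_scaling(latitude_of(grid, y_km), params) *
    dd_factor(crowding, params)
  mu[is_water_at(grid, x_km, y_km)] <- 0
  mu
}

#' Draw daughter-queen counts
#'
#' Poisson draws with the supplied mean(s), using R's global RNG (seed with
#' `set.seed` for reproducibility).
#'
#' @param mu Poisson mean(s), non-negative.
#' @param n number of draws; defaults to `length(mu)`.
#' @return non-negative integer vector.
#' @export
sample_offspring <- function(mu, n = length(mu)) {
  if (any(mu < 0)) stop("mu must be non-negative")
  stats::rpois(n, mu)
}

#' Read posterior parameter draws from CSV
#'
#' A headered CSV with one row per draw and columns named after
#' [demography_params()] fields (any subset). Rows are merged over the
#' defaults when sampled.
#'
#' @param path CSV path.
#' @return data.frame of class `posterior_draws`.
#' @export
read_posterior_draws <- function(path) {
  d <- utils::read.csv(path)
  as_posterior_draws(d)
}

#' @rdname read_posterior_draws
#' @param draws data.frame of parameter draws.
#' @export
as_posterior_draws <- function(draws) {
  known <- c("R_A", "lat_A_deg", "lat_zero_deg", "K_half", "r_c_km",
             "scaling_sigma")
  if (nrow(draws) < 1) stop("posterior draws table must have at least one row")
  bad <- setdiff(names(draws), known)
  if (length(bad) > 0)
    stop("unknown parameter column(s): ", paste(bad, collapse = ", "))
  class(draws) <- c("posterior_draws", "data.frame")
  draws
}

#' Sample one parameter set from posterior draws
#'
#' Uniformly samples a row of `draws` and merges it over `base`.
#'
#' @param draws a `posterior_draws` table (or `NULL`, returning `base`).
#' @param base default [demography_params()] providing unlisted fields.
#' @return a [demography_params()].
#' @export
sample_params <- function(draws, base = demography_params()) {
  if (is.null(draws)) return(base)
  if (nrow(draws) < 1) stop("posterior draws table is empty")
  row <- draws[sample.int(nrow(draws), 1L), , drop = FALSE]
  args <- as.list(base)[c("R_A", "lat_A_deg", "lat_zero_deg", "K_half",
                          "r_c_km", "scaling_sigma", "dd_form")]
  for (nm in names(row)) args[[nm]] <- row[[nm]]
  do.call(demography_params, args)
}
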