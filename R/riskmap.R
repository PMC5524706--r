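# Riskmap module: deterministic, simulation-free calculations on the
# probabilistic rates of the model. Given sighting locations it computes a
# founder-location posterior, propagates expected-nest intensity fields
# year by year (low-density linearisation: reproduction times the discrete
# settlement kernel), extracts high-risk contours, and solves the spatial
# branching-process extinction probability as a fixed point.

#' Expected-nest intensity field
#'
#' A grid-shaped matrix of expected nests per cell, in the same internal
#' orientation as [landscape_grid()] (row 1 = southernmost).
#'
#' @param values non-negative numeric matrix with the grid's dimensions.
#' @param grid the [landscape_grid()] frame.
#' @param year optional year label.
#' @return object of class `intensity_field`.
#' @export
intensity_field <- function(values, grid, year = NA_integer_) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  if (any(values < 0)) stop("intensity must be non-negative everywhere")
  structure(list(values = values, grid = grid, year = year),
            class = "intensity_field")
}

#' @export
print.intensity_field <- function(x, ...) {
  cat(sprintf("<intensity_field> %d x %d cells, total %.4g expected nests",
              nrow(x$values), ncol(x$values), field_total(x)))
  if (!is.na(x$year)) cat(sprintf(" (year %s)", x$year))
  cat("\n")
  invisible(x)
}

#' Total expected nests of an intensity field
#' @param field an [intensity_field()].
#' @return sum over cells.
#' @export
field_total <- function(field) sum(field$values)

#' Mode (highest-intensity cell) of a field
#' @param field an [intensity_field()].
#' @return list with `row`, `col`, `x_km`, `y_km` (cell centre), `value`.
#' @export
field_mode <- function(field) {
  i <- which.max(field$values)
  g <- field$grid
  row <- (i - 1L) %% g$n_rows + 1L
  col <- (i - 1L) %/% g$n_rows + 1L
  list(row = row, col = col,
       x_km = g$origin_x_km + (col - 0.5) * g$cell_km,
       y_km = g$origin_y_km + (row - 0.5) * g$cell_km,
       value = field$values[i])
}

#' Write an intensity field as an ESRI ASCII grid
#'
#' @param field an [intensity_field()].
#' @param path output path.
#' @param digits significant digits written.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path, digits = 8) {
  g <- field$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$n_cols),
               sprintf("nrows %d", g$n_rows),
               sprintf("xllcorner %.10g", g$origin_x_km),
               sprintf("yllcorner %.10g", g$origin_y_km),
               sprintf("cellsize %.10g", g$cell_km),
               "NODATA_value -9999"), con)
  m <- signif(field$values, digits)
  for (r in rev(seq_len(nrow(m))))
    writeLines(paste(m[r, ], collapse = " "), con)
  invisible(path)
}

#' Read a numeric raster written by [write_field()]
#'
#' Parses an ESRI ASCII grid of real values (intensities, probabilities,
#' masks) back into an [intensity_field()].
#'
#' @param path `.asc` path.
#' @param lat_at_origin_deg,km_per_degree_lat latitude frame.
#' @param year optional year label.
#' @return an [intensity_field()] (its `grid` carries a placeholder
#'   all-`other` class matrix: the `.asc` format stores values only).
#' @export
read_field <- function(path, lat_at_origin_deg = 50,
                       km_per_degree_lat = 111, year = NA_integer_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  header <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(header)))
    stop("malformed ESRI ASCII grid header in ", path)
  rows <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, rows)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  g <- landscape_grid(matrix(HABITAT_CODES[["other"]], nrow(m), ncol(m)),
                      cell_km = header$cellsize,
                      origin_x_km = header$xllcorner,
                      origin_y_km = header$yllcorner,
                      lat_at_origin_deg = lat_at_origin_deg,
                      km_per_degree_lat = km_per_degree_lat)
  intensity_field(m, g, year = year)
}

#' Read sighting records from CSV
#'
#' A headered CSV with columns `x_km`, `y_km`, and optionally `year` and
#' `type` (`nest` or `hornet`). A worker hornet sighting is treated as
#' evidence of a nest at the sighting location (workers forage near their
#' nest).
#'
#' @param path CSV path.
#' @return data.frame of observations.
#' @export
read_sightings <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("x_km", "y_km") %in% names(d)))
  d
}

# Cell-integrated 2-D dispersal density from a continuous point to every
# cell centre; same midpoint convention as the settlement kernel, with the
# observation's own cell integrated exactly over its equal-area radius.
point_kernel_field <- function(grid, x0, y0, disp) {
  cx <- cell_centers_x(grid); cy <- cell_centers_y(grid)
  d <- sqrt(outer((cy - y0)^2, (cx - x0)^2, `+`))
  v <- exp(-d / disp$delta_km) / (2 * pi * d * disp$delta_km) * grid$cell_km^2
  rc <- cell_row_col(grid, x0, y0)
  if (!is.na(rc$row)) {
    r_eq <- grid$cell_km / sqrt(pi)
    v[rc$row, rc$col] <- 1 - exp(-r_eq / disp$delta_km)
  }
  v
}

#' Posterior over founder-nest locations from sightings
#'
#' Each observed nest (or foraging hornet, taken as a proxy for a nearby
#' nest) is assumed to descend directly from a common founder via one
#' dispersal event. The posterior over founder cells is proportional to the
#' settleability indicator times the product over observations of the
#' cell-integrated 2-D dispersal density, normalised to sum to 1.
#'
#' @param observations data.frame with columns `x_km`, `y_km`.
#' @param grid a [landscape_grid()].
#' @param disp [dispersal_params()].
#' @param weights [suitability_weights()] (only the zero/non-zero pattern
#'   matters: cells with zero weight cannot host the founder).
#' @return normalised [intensity_field()] (a probability field).
#' @export
founder_posterior <- function(observations, grid,
                              disp = dispersal_params(),
                              weights = suitability_weights()) {
  observations <- as.data.frame(observations)
  if (nrow(observations) < 1) stop("at least one observation is required")
  logp <- matrix(0, grid$n_rows, grid$n_cols)
  for (i in seq_len(nrow(observations))) {
    v <- point_kernel_field(grid, observations$x_km[i],
                            observations$y_km[i], disp)
    logp <- logp + log(v)
  }
  logp[weights[grid$classes] == 0] <- -Inf
  if (all(!is.finite(logp)))
    stop("posterior is zero everywhere: observations unreachable from any ",
         "settleable cell")
  p <- exp(logp - max(logp[is.finite(logp)]))
  p[!is.finite(p)] <- 0
  intensity_field(p / sum(p), grid, year = 2015L)
}

# mu at zero crowding for every cell centre (0 on water).
mu0_field <- function(grid, dem) {
  mu_row <- dem$scaling_sigma * dem$R_A *
    latitude_scaling(latitude_of(grid, cell_centers_y(grid)), dem)
  mu <- matrix(mu_row, grid$n_rows, grid$n_cols)
  mu[grid$classes == HABITAT_CODES[["water"]]] <- 0
  mu
}

#' Propagate an intensity field by one generation
#'
#' Low-density linear propagation: `lambda'(y) = sum_x lambda(x) * mu0(x) *
#' T(x -> y)`, where `mu0` is the zero-crowding expected-queens mean and
#' `T` the discrete settlement kernel (its failure mass is dropped: failed
#' queens found no nest). Linear in `lambda`.
#'
#' @param field an [intensity_field()].
#' @param dem [demography_params()].
#' @param disp [dispersal_params()].
#' @param weights [suitability_weights()].
#' @param model optional precomputed settlement model (internal reuse).
#' @return the next-generation [intensity_field()].
#' @export
propagate_intensity <- function(field, dem = demography_params(),
                                disp = dispersal_params(),
                                weights = suitability_weights(),
                                model = NULL) {
  grid <- field$grid
  if (is.null(model)) model <- settlement_model(grid, weights, disp)
  src <- field$values * mu0_field(grid, dem) * model$cfac
  out <- model$a * conv2_fft(src, K_fft = model$plan)
  out[out < 0] <- 0   # FFT round-off
  intensity_field(out, grid,
                  year = if (is.na(field$year)) NA_integer_ else
                    field$year + 1L)
}

#' Expected undiscovered nests in the year of discovery
#'
#' One generation of propagation of the founder posterior. Because
#' daughter-nest counts are Poisson, independent detection and destruction
#' of nests is a Poisson thinning: removing the discovered nest leaves the
#' distribution of the remaining (undiscovered) nests unchanged, so no
#' conditioning correction is applied. The field total is the expected
#' number of additional daughter nests; `1 - exp(-total)` is the
#' probability at least one nest remains undiscovered.
#'
#' @param founder normalised founder posterior ([founder_posterior()]).
#' @inheritParams propagate_intensity
#' @return [intensity_field()] of expected undiscovered nests.
#' @export
undiscovered_nests <- function(founder, dem = demography_params(),
                               disp = dispersal_params(),
                               weights = suitability_weights(),
                               model = NULL) {
  stopifnot(abs(field_total(founder) - 1) < 1e-6)
  propagate_intensity(founder, dem, disp, weights, model)
}

#' Expected new nests one further year on
#'
#' @param field_2016 the undiscovered-nest field ([undiscovered_nests()]).
#' @inheritParams propagate_intensity
#' @return [intensity_field()] for the following year.
#' @export
next_year_nests <- function(field_2016, dem = demography_params(),
                            disp = dispersal_params(),
                            weights = suitability_weights(),
                            model = NULL) {
  propagate_intensity(field_2016, dem, disp, weights, model)
}

#' High-risk region of an intensity field
#'
#' The smallest set of highest-intensity cells such that the expected
#' number of nests outside the set is below `budget` (default: less than
#' one nest expected outside the contour).
#'
#' @param field an [intensity_field()].
#' @param budget expected nests allowed outside the region.
#' @return list with `mask` (logical matrix), `area_km2`, `level` (lowest
#'   included intensity; `Inf` for an empty region) and `outside`
#'   (expected nests left outside).
#' @export
high_risk_region <- function(field, budget = 1.0) {
  v <- as.vector(field$values)
  total <- sum(v)
  mask <- matrix(FALSE, nrow(field$values), ncol(field$values))
  if (total < budget) {
    return(list(mask = mask, area_km2 = 0, level = Inf, outside = total))
  }
  ord <- order(v, decreasing = TRUE)
  cum <- cumsum(v[ord])
  k <- which(total - cum < budget)[1]
  mask[ord[seq_len(k)]] <- TRUE
  list(mask = mask, area_km2 = k * field$grid$cell_km^2,
       level = v[ord[k]], outside = total - cum[k])
}

#' Branching-process extinction probability field
#'
#' Low-density approximation (no density dependence, valid near the
#' extinction threshold): the lineage of a nest at cell `x` dies out with
#' probability `q(x)` solving
#' `q(x) = exp( mu0(x) * ( sum_y T(x->y) q(y) + fail(x) - 1 ) )`,
#' the Poisson-offspring fixed point with dispersal kernel `T` and
#' settlement failure mass `fail`. Solved by monotone iteration from
#' `q = 0` (converging to the minimal fixed point, the true extinction
#' probability), with a geometric-tail stopping rule on the sup-norm
#' change.
#'
#' @param grid a [landscape_grid()].
#' @param dem [demography_params()].
#' @param disp [dispersal_params()].
#' @param weights [suitability_weights()].
#' @param at optional `c(x_km, y_km)`; if given, `value` is `q` there.
#' @param tol sup-norm convergence tolerance.
#' @param max_iter iteration cap.
#' @param model optional precomputed settlement model.
#' @return list with `q` (matrix field), `value` (`q` at `at`, or `NA`),
#'   `iterations`, `converged`.
#' @export
extinction_probability <- function(grid, dem = demography_params(),
                                   disp = dispersal_params(),
                                   weights = suitability_weights(),
                                   at = NULL, tol = 1e-9,
                                   max_iter = 50000L, model = NULL) {
  if (is.null(model)) model <- settlement_model(grid, weights, disp)
  mu0 <- mu0_field(grid, dem)
  q <- matrix(0, grid$n_rows, grid$n_cols)
  delta_prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    reach <- model$cfac * conv2_fft(model$a * q, K_fft = model$plan)
    reach <- pmin(pmax(reach, 0), 1)
    q_new <- exp(mu0 * (reach + model$fail - 1))
    delta <- max(abs(q_new - q))
    q <- q_new
    if (delta < tol) { converged <- TRUE; break }
    # geometric-tail bound: remaining error ~ delta * r / (1 - r)
    if (is.finite(delta_prev) && delta_prev > 0) {
      r <- delta / delta_prev
      if (it >= 10L && r < 1 && delta * r / (1 - r) < tol) {
        converged <- TRUE; break
      }
    }
    delta_prev <- delta
  }
  if (!converged)
    warning("extinction fixed point not converged after ", max_iter,
            " iterations (last change ", signif(delta, 3), ")")
  value <- NA_real_
  if (!is.null(at)) {
    rc <- cell_row_col(grid, at[1], at[2])
    if (!is.na(rc$row)) value <- q[rc$row, rc$col]
  }
  list(q = q, value = value, iterations = it, converged = converged)
}

# Demography with the latitude cline re-anchored so the realised
# reproductive ratio at lat_deg equals `ratio` (1 kept at Andernos), or
# with a flat multiplier achieving the same realised ratio.
params_for_ratio <- function(ratio, lat_deg, base, vary) {
  if (vary == "cline") {
    if (ratio >= 1) stop("cline mode requires realised ratio < 1")
    p <- base
    p$lat_zero_deg <- lat_zero_for_ratio(ratio, lat_deg, base$lat_A_deg)
    p
  } else {
    base_ratio <- latitude_scaling(lat_deg, base)
    p <- base
    p$scaling_sigma <- base$scaling_sigma * ratio / base_ratio
    p
  }
}

#' Sensitivity of the risk-map outputs to reproductive potential
#'
#' Re-runs the risk-map pipeline over a sweep of the realised reproductive
#' ratio at the founder location (the fraction of the Andernos-les-Bains
#' baseline realised there, the natural x-axis for GB sensitivity
#' analyses). In `vary = "multiplier"` mode (default) the slope of the
#' linear latitude function is scaled about its fixed northern zero cline,
#' which is equivalent to a flat multiplier on reproductive potential; as
#' the ratio shrinks the whole map becomes subcritical, so extinction
#' becomes certain in the small-ratio limit. In `vary = "cline"` mode the
#' zero cline itself is moved so the founder realises the target ratio
#' while Andernos keeps ratio 1; note that this leaves terrain south of
#' the founder super-baseline relative to the founder, so even tiny
#' founder ratios need not imply map-wide extinction.
#'
#' @param ratios realised reproductive ratios to evaluate (in `[0, 1)` for
#'   cline mode).
#' @param observations sightings for the founder posterior.
#' @param grid a [landscape_grid()].
#' @param dem base [demography_params()].
#' @param disp [dispersal_params()].
#' @param weights [suitability_weights()].
#' @param vary `"multiplier"` (default) or `"cline"`.
#' @param budget high-risk contour budget.
#' @return data.frame with columns `ratio`, `nests_yr1`, `nests_yr2`,
#'   `extinction_prob`, `area_yr1_km2`, `area_yr2_km2`.
#' @export
sensitivity_curves <- function(ratios, observations, grid,
                               dem = demography_params(),
                               disp = dispersal_params(),
                               weights = suitability_weights(),
                               vary = c("multiplier", "cline"),
                               budget = 1.0) {
  vary <- match.arg(vary)
  model <- settlement_model(grid, weights, disp)
  post <- founder_posterior(observations, grid, disp, weights)
  mode <- field_mode(post)
  lat_f <- latitude_of(grid, mode$y_km)
  out <- lapply(ratios, function(rho) {
    p <- params_for_ratio(rho, lat_f, dem, vary)
    f1 <- propagate_intensity(post, p, disp, weights, model)
    f2 <- propagate_intensity(f1, p, disp, weights, model)
    ext <- extinction_probability(grid, p, disp, weights,
                                  at = c(mode$x_km, mode$y_km),
                                  model = model)
    data.frame(ratio = rho,
               nests_yr1 = field_total(f1), nests_yr2 = field_total(f2),
               extinction_prob = ext$value,
               area_yr1_km2 = high_risk_region(f1, budget)$area_km2,
               area_yr2_km2 = high_risk_region(f2, budget)$area_km2)
  })
  do.call(rbind, out)
}

#' Largest reproductive ratio with near-certain extinction
#'
#' Scans the realised reproductive ratio at the founder location upward
#' (multiplier mode of [sensitivity_curves()] by default) and returns the
#' largest ratio at which the branching-process extinction probability at
#' the founder mode is at least `q_min`.
#'
#' @param observations sightings for the founder posterior.
#' @param grid a [landscape_grid()].
#' @param dem,disp,weights model parameters.
#' @param q_min extinction-probability threshold (default 0.99).
#' @param step scan step in ratio units.
#' @param max_ratio scan upper bound.
#' @param vary `"multiplier"` (default) or `"cline"`.
#' @return list with `threshold` (largest qualifying ratio) and the scan
#'   `table` (`ratio`, `extinction_prob`).
#' @export
extinction_threshold <- function(observations, grid,
                                 dem = demography_params(),
                                 disp = dispersal_params(),
                                 weights = suitability_weights(),
                                 q_min = 0.99, step = 0.0025,
                                 max_ratio = 0.25,
                                 vary = c("multiplier", "cline")) {
  vary <- match.arg(vary)
  model <- settlement_model(grid, weights, disp)
  post <- founder_posterior(observations, grid, disp, weights)
  mode <- field_mode(post)
  lat_f <- latitude_of(grid, mode$y_km)
  ratios <- seq(step, max_ratio, by = step)
  tab <- data.frame(ratio = numeric(0), extinction_prob = numeric(0))
  threshold <- 0
  for (rho in ratios) {
    p <- params_for_ratio(rho, lat_f, dem, vary)
    ext <- extinction_probability(grid, p, disp, weights,
                                  at = c(mode$x_km, mode$y_km),
                                  model = model)
    tab <- rbind(tab, data.frame(ratio = rho,
                                 extinction_prob = ext$value))
    if (ext$value >= q_min) threshold <- rho else break
  }
  list(threshold = threshold, table = tab)
}
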