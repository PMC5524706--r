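# Landscape module: habitat raster representation, ESRI ASCII grid I/O,
# latitude conventions and a synthetic coastal landscape generator.
#
# Coordinates are projected kilometres with y = northing. Internally the
# class matrix is stored row-major with row 1 = southernmost row; the ESRI
# ASCII file order (top row = northernmost) is converted on I/O. Cell centres
# stand for cell locations in all kernel computations; nests themselves carry
# continuous coordinates and cells only classify habitat.

HABITAT_CODES <- c(urban = 1L, agricultural = 2L, woodland = 3L,
                   other = 4L, water = 5L)

#' Habitat classes
#'
#' The five-class habitat scheme used throughout the package: urban,
#' agricultural, woodland, other and water. Water is the only class that can
#' never host a nest. Users mapping real land-cover products (e.g. Corine)
#' must re-map their codes onto these five.
#'
#' @return a data.frame with columns `code` and `name`.
#' @export
#' @examples
#' habitat_classes()
habitat_classes <- function() {
  data.frame(code = unname(HABITAT_CODES), name = names(HABITAT_CODES))
}

#' Habitat suitability weights
#'
#' Relative settlement preferences per habitat class. Urban and agricultural
#' terrain are preferred; water is unsettleable and must have weight zero.
#' Weights are relative (only ratios matter): settlement accepts a candidate
#' destination with probability `weight / max(weight)`.
#'
#' @param urban,agricultural,woodland,other,water non-negative weights.
#' @return named numeric vector of class weights.
#' @export
#' @examples
#' suitability_weights()
#' suitability_weights(woodland = 0.8)
suitability_weights <- function(urban = 1, agricultural = 1, woodland = 0.5,
                                other = 0.25, water = 0) {
  w <- c(urban = urban, agricultural = agricultural, woodland = woodland,
         other = other, water = water)
  if (any(w < 0)) stop("suitability weights must be non-negative")
  if (w[["water"]] != 0) stop("water must have weight 0 (cannot host a nest)")
  if (all(w == 0)) stop("at least one habitat class must have positive weight")
  w
}

#' Construct a landscape grid
#'
#' @param classes integer matrix of habitat codes (see [habitat_classes()]),
#'   row 1 = southernmost row, column 1 = westernmost column.
#' @param cell_km cell size in km (default 1, i.e. 1-km squares).
#' @param origin_x_km,origin_y_km coordinates of the lower-left (south-west)
#'   corner of the grid.
#' @param lat_at_origin_deg latitude (degrees north) of the southern edge.
#' @param km_per_degree_lat km of northing per degree of latitude
#'   (default 111); `Inf` gives a latitude-flat landscape, used for
#'   constant-latitude baseline experiments.
#' @return an object of class `landscape_grid`.
#' @export
landscape_grid <- function(classes, cell_km = 1, origin_x_km = 0,
                           origin_y_km = 0, lat_at_origin_deg = 50,
                           km_per_degree_lat = 111) {
  classes <- as.matrix(classes)
  storage.mode(classes) <- "integer"
  if (nrow(classes) < 1L || ncol(classes) < 1L)
    stop("landscape grid must have at least one row and one column")
  if (!all(classes %in% HABITAT_CODES))
    stop("unknown habitat class code(s): ",
         paste(setdiff(unique(as.vector(classes)), HABITAT_CODES), collapse = ", "))
  if (!is.finite(cell_km) || cell_km <= 0) stop("cell_km must be positive")
  if (km_per_degree_lat <= 0) stop("km_per_degree_lat must be positive")
  structure(list(classes = classes,
                 n_rows = nrow(classes), n_cols = ncol(classes),
                 cell_km = cell_km,
                 origin_x_km = origin_x_km, origin_y_km = origin_y_km,
                 lat_at_origin_deg = lat_at_origin_deg,
                 km_per_degree_lat = km_per_degree_lat),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> %d x %d cells of %g km (%g x %g km)\n",
              x$n_rows, x$n_cols, x$cell_km,
              x$n_cols * x$cell_km, x$n_rows * x$cell_km))
  cat(sprintf("  origin (%g, %g) km; latitude %g degN at southern edge",
              x$origin_x_km, x$origin_y_km, x$lat_at_origin_deg))
  if (is.finite(x$km_per_degree_lat)) {
    cat(sprintf(", %g km/deg\n", x$km_per_degree_lat))
  } else {
    cat(" (latitude-flat)\n")
  }
  p <- prop.table(table(factor(x$classes, levels = HABITAT_CODES,
                               labels = names(HABITAT_CODES))))
  cat("  cover:", paste(sprintf("%s %.1f%%", names(p), 100 * p), collapse = ", "),
      "\n")
  invisible(x)
}

#' Latitude of a northing coordinate
#'
#' Latitude is modelled as an affine function of northing:
#' `lat_at_origin_deg + (y_km - origin_y_km) / km_per_degree_lat`. This
#' preserves the only geographic property the demographic model uses, a
#' linear north--south gradient.
#'
#' @param grid a [landscape_grid()].
#' @param y_km northing coordinate(s) in km.
#' @return latitude in degrees north (vectorised).
#' @export
#' @examples
#' g <- landscape_grid(matrix(2L, 5, 5), lat_at_origin_deg = 50)
#' latitude_of(g, 111)  # one degree north of the origin
latitude_of <- function(grid, y_km) {
  if (is.infinite(grid$km_per_degree_lat)) {
    rep(grid$lat_at_origin_deg, length(y_km))
  } else {
    grid$lat_at_origin_deg + (y_km - grid$origin_y_km) / grid$km_per_degree_lat
  }
}

# Row/column of the cell containing (x, y); NA outside the grid.
cell_row_col <- function(grid, x_km, y_km) {
  col <- floor((x_km - grid$origin_x_km) / grid$cell_km) + 1
  row <- floor((y_km - grid$origin_y_km) / grid$cell_km) + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

# Habitat code at continuous coordinates; NA outside the grid.
class_at <- function(grid, x_km, y_km) {
  rc <- cell_row_col(grid, x_km, y_km)
  out <- rep(NA_integer_, length(rc$row))
  ok <- !is.na(rc$row)
  out[ok] <- grid$classes[cbind(rc$row[ok], rc$col[ok])]
  out
}

is_water_at <- function(grid, x_km, y_km) {
  cl <- class_at(grid, x_km, y_km)
  is.na(cl) | cl == HABITAT_CODES[["water"]]
}

# Cell-centre coordinate vectors (length n_rows / n_cols).
cell_centers_y <- function(grid)
  grid$origin_y_km + (seq_len(grid$n_rows) - 0.5) * grid$cell_km
cell_centers_x <- function(grid)
  grid$origin_x_km + (seq_len(grid$n_cols) - 0.5) * grid$cell_km

#' Read an ESRI ASCII grid of habitat classes
#'
#' Parses the standard `.asc` dialect: a header with keys `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize` and optionally `NODATA_value`,
#' followed by `nrows` whitespace-separated data rows, the first file row
#' being the northernmost. NODATA cells are mapped to water.
#'
#' @param path path to the `.asc` file.
#' @param lat_at_origin_deg,km_per_degree_lat latitude frame of the grid (the
#'   `.asc` format itself does not carry one).
#' @return a [landscape_grid()].
#' @export
read_grid <- function(path, lat_at_origin_deg = 50, km_per_degree_lat = 111) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("malformed ESRI ASCII grid: empty file")
  header <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing_keys <- setdiff(need, names(header))
  if (length(missing_keys) > 0)
    stop("malformed ESRI ASCII grid header: missing ",
         paste(missing_keys, collapse = ", "))
  ncols <- as.integer(header$ncols); nrows <- as.integer(header$nrows)
  if (ncols < 1 || nrows < 1) stop("ESRI ASCII grid must be non-empty")
  data_lines <- lines[i:length(lines)]
  if (length(data_lines) != nrows)
    stop("ESRI ASCII grid: expected ", nrows, " data rows, found ",
         length(data_lines))
  rows <- lapply(data_lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (anyNA(v)) stop("ESRI ASCII grid: non-numeric entry in data row")
    v
  })
  if (any(lengths(rows) != ncols))
    stop("ESRI ASCII grid: data row length does not match ncols")
  m <- do.call(rbind, rows)          # file order: row 1 = north
  if (!is.null(header$nodata_value))
    m[m == header$nodata_value] <- HABITAT_CODES[["water"]]
  m <- m[rev(seq_len(nrows)), , drop = FALSE]  # internal order: row 1 = south
  bad <- setdiff(unique(as.vector(m)), HABITAT_CODES)
  if (length(bad) > 0)
    stop("ESRI ASCII grid: unknown habitat class code(s): ",
         paste(bad, collapse = ", "))
  landscape_grid(m, cell_km = header$cellsize,
                 origin_x_km = header$xllcorner,
                 origin_y_km = header$yllcorner,
                 lat_at_origin_deg = lat_at_origin_deg,
                 km_per_degree_lat = km_per_degree_lat)
}

#' Write a landscape grid (or intensity field) as an ESRI ASCII grid
#'
#' @param grid a [landscape_grid()], or a numeric matrix in the internal
#'   row-1-south orientation together with `meta`.
#' @param path output path.
#' @param nodata NODATA value written in the header (no cell uses it for
#'   class grids; water keeps its own code so I/O round-trips exactly).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, nodata = -9999) {
  if (inherits(grid, "landscape_grid")) {
    m <- grid$classes; meta <- grid
  } else stop("write_grid expects a landscape_grid; see write_field for fields")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", meta$n_cols),
               sprintf("nrows %d", meta$n_rows),
               sprintf("xllcorner %.10g", meta$origin_x_km),
               sprintf("yllcorner %.10g", meta$origin_y_km),
               sprintf("cellsize %.10g", meta$cell_km),
               sprintf("NODATA_value %g", nodata)), con)
  for (r in rev(seq_len(nrow(m))))   # top file row = northernmost
    writeLines(paste(m[r, ], collapse = " "), con)
  invisible(path)
}

#' Generate a synthetic coastal landscape
#'
#' Builds a random landscape whose class proportions match a target
#' specification, with spatially autocorrelated habitat patches and a
#' contiguous water margin emulating a coastline along the southern and
#' western edges. The output is a pure function of the arguments and seed.
#'
#' Patches are produced by thresholding Gaussian-smoothed white noise at the
#' exact target quantiles, so realised proportions equal the targets up to
#' rounding to whole cells.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell_km cell size in km.
#' @param proportions named vector of target class proportions (subset of
#'   `urban`, `agricultural`, `woodland`, `water`); must be non-negative and
#'   sum to at most 1, the remainder becomes `other`.
#' @param patch_km patch correlation length in km.
#' @param coast if `TRUE` the water fraction forms a coastal margin along the
#'   south and west edges; if `FALSE` water is patchy like other classes.
#' @param seed integer seed; identical arguments and seed give identical output.
#' @param origin_x_km,origin_y_km,lat_at_origin_deg,km_per_degree_lat
#'   coordinate frame, passed to [landscape_grid()].
#' @return a [landscape_grid()].
#' @export
#' @examples
#' g <- generate_landscape(60, 60, seed = 1)
#' table(g$classes) / length(g$classes)
generate_landscape <- function(n_rows, n_cols, cell_km = 1,
                               proportions = c(urban = 0.08,
                                               agricultural = 0.55,
                                               woodland = 0.12,
                                               water = 0.15),
                               patch_km = 10, coast = TRUE, seed = 1,
                               origin_x_km = 0, origin_y_km = 0,
                               lat_at_origin_deg = 50,
                               km_per_degree_lat = 111) {
  allowed <- c("urban", "agricultural", "woodland", "water")
  if (!all(names(proportions) %in% allowed))
    stop("proportions may only name: ", paste(allowed, collapse = ", "))
  p <- setNames(numeric(4), allowed)
  p[names(proportions)] <- proportions
  if (any(p < 0)) stop("class proportions must be non-negative")
  if (sum(p) > 1 + 1e-12) stop("class proportions must sum to at most 1")
  p_other <- 1 - sum(p)

  with_seed(seed, {
    n <- n_rows * n_cols
    smooth_field <- function() {
      z <- matrix(stats::rnorm(n), n_rows, n_cols)
      s <- max(patch_km / cell_km, 0.5)
      half <- ceiling(3 * s)
      ax <- stats::dnorm(seq(-half, half), sd = s)
      K <- outer(ax, ax)
      f <- conv2_fft(z, K / sum(K))
      (f - mean(f)) / stats::sd(f)
    }

    cl <- matrix(HABITAT_CODES[["other"]], n_rows, n_cols)
    n_water <- round(p[["water"]] * n)
    if (n_water > 0) {
      if (coast) {
        # score = scaled distance to the SW edges + smooth noise; lowest
        # scores (nearest the coast) become water, giving a ragged margin.
        dx <- matrix(rep(seq_len(n_cols) - 0.5, each = n_rows), n_rows, n_cols)
        dy <- matrix(rep(seq_len(n_rows) - 0.5, n_cols), n_rows, n_cols)
        edge <- pmin(dx / n_cols, dy / n_rows)
        score <- 6 * edge + smooth_field()
      } else {
        score <- smooth_field()
      }
      thr <- sort(as.vector(score), partial = n_water)[n_water]
      cl[score <= thr] <- HABITAT_CODES[["water"]]
    }

    land <- which(cl != HABITAT_CODES[["water"]])
    if (length(land) > 0) {
      z <- smooth_field()[land]
      # rank-split land cells into the remaining classes at exact quantiles
      land_p <- c(p[["urban"]], p[["agricultural"]], p[["woodland"]], p_other)
      if (sum(land_p) > 0) {
        land_p <- land_p / sum(land_p)
        counts <- floor(land_p * length(land))
        rem <- length(land) - sum(counts)
        if (rem > 0) {  # distribute remainder by largest fractional part
          fr <- land_p * length(land) - counts
          counts[order(fr, decreasing = TRUE)[seq_len(rem)]] <-
            counts[order(fr, decreasing = TRUE)[seq_len(rem)]] + 1
        }
        codes <- c(HABITAT_CODES[["urban"]], HABITAT_CODES[["agricultural"]],
                   HABITAT_CODES[["woodland"]], HABITAT_CODES[["other"]])
        ord <- land[order(z)]
        cl[ord] <- rep(codes, times = counts)
      }
    }
    landscape_grid(cl, cell_km = cell_km,
                   origin_x_km = origin_x_km, origin_y_km = origin_y_km,
                   lat_at_origin_deg = lat_at_origin_deg,
                   km_per_degree_lat = km_per_degree_lat)
  })
}
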