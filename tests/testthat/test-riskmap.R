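test_that("the founder posterior is a probability field with sane support", {
  g <- patchy_grid()
  obs <- data.frame(x_km = c(40, 70), y_km = c(60, 55))
  post <- founder_posterior(obs, g)
  expect_equal(field_total(post), 1, tolerance = 1e-12)
  expect_true(all(post$values[g$classes == 5L] == 0))
  # order of observations is irrelevant
  post_rev <- founder_posterior(obs[2:1, ], g)
  expect_equal(post$values, post_rev$values, tolerance = 1e-12)

  # a single observation is best explained by a founder in its own cell
  p1 <- founder_posterior(data.frame(x_km = 61, y_km = 61), g)
  m1 <- field_mode(p1)
  expect_lt(sqrt((m1$x_km - 61)^2 + (m1$y_km - 61)^2), 2 * g$cell_km)
})

test_that("the two-sighting posterior peaks on the segment between them", {
  g <- flat_grid(extent_km = 400, cell_km = 4)
  a <- c(150, 200); b <- c(250, 200)
  post <- founder_posterior(data.frame(x_km = c(a[1], b[1]),
                                       y_km = c(a[2], b[2])), g)
  m <- field_mode(post)
  # distance from the mode cell centre to the segment, within one cell
  expect_lt(abs(m$y_km - 200), g$cell_km)
  expect_gte(m$x_km, a[1] - g$cell_km)
  expect_lte(m$x_km, b[1] + g$cell_km)
})

test_that("propagation is linear with exact kernel bookkeeping", {
  g <- patchy_grid()
  zero <- intensity_field(matrix(0, g$n_rows, g$n_cols), g)
  expect_equal(field_total(propagate_intensity(zero)), 0)

  # a unit point mass propagates to total mu0 * (1 - failure mass)
  v <- matrix(0, g$n_rows, g$n_cols)
  v[25, 35] <- 1
  f <- intensity_field(v, g)
  out <- propagate_intensity(f)
  cx <- hornetspread:::cell_centers_x(g)[35]
  cy <- hornetspread:::cell_centers_y(g)[25]
  mu0 <- expected_queens(cx, cy, 0, g)
  k <- settlement_kernel(c(25, 35), g)
  expect_equal(field_total(out), mu0 * (1 - k$fail), tolerance = 1e-8)

  f2 <- intensity_field(2 * v, g)
  expect_equal(propagate_intensity(f2)$values, 2 * out$values,
               tolerance = 1e-12)
})

test_that("analytic propagation matches the stochastic one-year mean", {
  g <- patchy_grid()
  cx <- hornetspread:::cell_centers_x(g)[30]
  cy <- hornetspread:::cell_centers_y(g)[28]
  v <- matrix(0, g$n_rows, g$n_cols); v[28, 30] <- 1
  lam <- propagate_intensity(intensity_field(v, g))

  set.seed(51)
  n <- 1e4
  acc <- matrix(0, g$n_rows, g$n_cols)
  counts <- numeric(n)
  for (i in seq_len(n)) {
    out <- hornetspread:::advance_nests(cx, cy, g, demography_params(),
                                        dispersal_params(),
                                        suitability_weights())
    counts[i] <- length(out$x)
    if (length(out$x) > 0) {
      rc <- hornetspread:::cell_row_col(g, out$x, out$y)
      idx <- (rc$col - 1L) * g$n_rows + rc$row
      acc <- acc + tabulate(idx, nbins = g$n_rows * g$n_cols)
    }
  }
  # total expected daughters
  expect_lt(abs(mean(counts) - field_total(lam)),
            3 * sd(counts) / sqrt(n))
  # aggregated into coarse 10x10-cell blocks, each within 3 SE
  block <- function(m) {
    sapply(split(seq_len(60), rep(1:6, each = 10)), function(cols)
      sapply(split(seq_len(60), rep(1:6, each = 10)), function(rows)
        sum(m[rows, cols])))
  }
  mc <- block(acc) / n
  an <- block(lam$values)
  se <- sqrt(pmax(mc, 1e-4) / n)  # Poisson-ish per-block error
  expect_true(all(abs(mc - an) <= 3 * se + 1e-3))
})

test_that("detection thinning leaves undiscovered nests Poisson", {
  g <- patchy_grid()
  cx <- hornetspread:::cell_centers_x(g)[30]
  cy <- hornetspread:::cell_centers_y(g)[28]
  v <- matrix(0, g$n_rows, g$n_cols); v[28, 30] <- 1
  mu_tot <- field_total(propagate_intensity(intensity_field(v, g)))
  p_det <- 0.3
  set.seed(52)
  n <- 1e4
  remaining <- integer(0)
  for (i in seq_len(n)) {
    out <- hornetspread:::advance_nests(cx, cy, g, demography_params(),
                                        dispersal_params(),
                                        suitability_weights())
    k <- length(out$x)
    det <- if (k > 0) sum(runif(k) < p_det) else 0L
    if (det == 1L) remaining <- c(remaining, k - 1L)
  }
  # conditioned on exactly one detected (and removed) nest, the rest are
  # Poisson with the thinned mean
  lambda <- (1 - p_det) * mu_tot
  brk <- c(0:6, Inf)
  obs <- table(cut(remaining, breaks = c(-1, 0:5, Inf)))
  probs <- c(dpois(0:5, lambda), ppois(5, lambda, lower.tail = FALSE))
  expect_gt(chisq.test(as.vector(obs), p = probs)$p.value, 0.01)
})

test_that("high-risk regions are minimal prefix sets", {
  g <- landscape_grid(matrix(2L, 10, 10), cell_km = 2)
  set.seed(53)
  for (i in 1:10) {
    f <- intensity_field(matrix(rexp(100, 2), 10, 10), g)
    hr <- high_risk_region(f, budget = 1)
    outside <- field_total(f) - sum(f$values[hr$mask])
    expect_lt(outside, 1)
    if (any(hr$mask)) {
      # dropping the least intense included cell must break the budget
      expect_gte(outside + hr$level, 1)
      expect_equal(hr$area_km2, sum(hr$mask) * 4)
    }
  }
  tiny <- intensity_field(matrix(0.001, 10, 10), g)
  hr0 <- high_risk_region(tiny, budget = 1)
  expect_equal(hr0$area_km2, 0)
  expect_false(any(hr0$mask))
  # larger budgets can only shrink the region
  f <- intensity_field(matrix(rexp(100, 1), 10, 10), g)
  a1 <- high_risk_region(f, 0.5)$area_km2
  a2 <- high_risk_region(f, 2)$area_km2
  expect_lte(a2, a1)
})

test_that("extinction probability solves the branching fixed point", {
  # zero reproduction: extinction certain everywhere
  g <- flat_grid(extent_km = 240, cell_km = 4)
  ext0 <- extinction_probability(g, demography_params(scaling_sigma = 0))
  expect_true(all(ext0$q == 1))

  # homogeneous landscape with a short kernel: the interior solution must
  # match the scalar Poisson fixed point q = exp(mu (q - 1))
  dem <- demography_params(R_A = 2)
  disp <- dispersal_params(delta_km = 6)
  ext <- extinction_probability(g, dem, disp, at = c(120, 120))
  expect_true(ext$converged)
  q_scalar <- uniroot(function(q) q - exp(2 * (q - 1)), c(1e-9, 1 - 1e-9),
                      tol = 1e-12)$root
  expect_lt(abs(ext$value - q_scalar), 0.02)
  expect_true(all(ext$q >= 0 & ext$q <= 1))
})

test_that("sensitivity curves move monotonically with reproductive ratio", {
  g <- gb_landscape(cell_km = 8)
  obs <- gb_sightings()
  tab <- sensitivity_curves(c(0, 0.2, 0.4), obs, g)
  expect_equal(tab$nests_yr1[1], 0)
  expect_equal(tab$extinction_prob[1], 1)
  expect_equal(tab$area_yr1_km2[1], 0)
  expect_true(all(diff(tab$nests_yr1) > 0))
  expect_true(all(diff(tab$nests_yr2) > 0))
  expect_true(all(diff(tab$extinction_prob) <= 0))
  expect_true(all(diff(tab$area_yr2_km2) >= 0))
})

test_that("numeric rasters round-trip through write_field and read_field", {
  g <- patchy_grid(n = 20)
  f <- intensity_field(matrix(runif(400), 20, 20), g, year = 2016L)
  path <- withr::local_tempfile(fileext = ".asc")
  write_field(f, path)
  back <- read_field(path)
  expect_equal(back$values, f$values, tolerance = 1e-7)
  expect_equal(back$grid$cell_km, g$cell_km)
})
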