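test_that("a nest with zero reproductive mean leaves no descendants", {
  g <- flat_grid()
  dem <- demography_params(scaling_sigma = 0)
  set.seed(31)
  nxt <- step_year(single_nest(200, 200), 1, g, dem)
  expect_equal(nrow(nxt), 0)
})

test_that("one-year mean offspring equals mu times settlement success", {
  g <- flat_grid(extent_km = 800)
  dem <- demography_params(R_A = 2)   # flat latitude: mu = 2 at zero crowding
  k <- settlement_kernel(c(100, 100), g)  # centre cell of 4-km grid
  expected <- 2 * (1 - k$fail)
  # mothers spaced 10 km > r_c apart (zero crowding), far from the edges;
  # per-mother daughter counts are then iid across mothers and repeats
  xy <- expand.grid(x = seq(300, 500, by = 10), y = seq(300, 500, by = 10))
  set.seed(32)
  kids <- unlist(lapply(1:25, function(i) {
    out <- hornetspread:::advance_nests(xy$x, xy$y, g, dem,
                                        dispersal_params(),
                                        suitability_weights())
    tabulate(out$parent, nbins = nrow(xy))
  }))
  se <- sd(kids) / sqrt(length(kids))
  expect_lt(abs(mean(kids) - expected), 3 * se)
})

test_that("low-density growth follows the branching mean for early years", {
  g <- flat_grid(extent_km = 600)
  dem <- demography_params(R_A = 1.8, K_half = 1e6)  # negligible competition
  sc <- scenario(g, data.frame(x_km = 300, y_km = 300), years = 4,
                 n_replicates = 2000, dem = dem, master_seed = 33)
  runs <- run_invasion(sc)
  counts <- sapply(runs, `[[`, "counts")
  for (t in 2:4) {
    m <- mean(counts[t, ])
    se <- sd(counts[t, ]) / sqrt(ncol(counts))
    expect_lt(abs(m - 1.8^(t - 1)), 3 * se + 0.02)
  }
})

test_that("runs are reproducible and extinction is absorbing", {
  g <- flat_grid()
  dem <- demography_params(R_A = 1.2)
  sc <- scenario(g, data.frame(x_km = 200, y_km = 200), years = 12,
                 n_replicates = 30, dem = dem, master_seed = 7)
  r1 <- run_invasion(sc)
  r2 <- run_invasion(sc)
  expect_identical(lapply(r1, `[[`, "counts"), lapply(r2, `[[`, "counts"))
  expect_identical(lapply(r1, `[[`, "front_km"), lapply(r2, `[[`, "front_km"))
  for (tr in r1) {
    z <- which(tr$counts == 0)
    if (length(z) > 0) {
      expect_true(all(tr$counts[z[1]:length(tr$counts)] == 0))
      expect_equal(tr$extinct_year, z[1])
      expect_equal(tr$outcome, "extinct")
    }
  }
})

test_that("trajectory summaries are coherent order statistics", {
  g <- flat_grid()
  sc <- scenario(g, data.frame(x_km = 200, y_km = 200), years = 6,
                 n_replicates = 50, dem = demography_params(R_A = 1.5),
                 master_seed = 8)
  s <- trajectory_summary(run_invasion(sc))
  expect_equal(names(s), c("year", "mean", "median", "q025", "q25", "q75",
                           "q975"))
  expect_equal(nrow(s), 6)
  expect_true(all(s$q025 <= s$q25 & s$q25 <= s$median &
                  s$median <= s$q75 & s$q75 <= s$q975))
  expect_equal(s$mean[1], 1)  # the single founding nest
})

test_that("nest density rasters conserve counts", {
  g <- flat_grid(extent_km = 40, cell_km = 4)
  sc <- scenario(g, data.frame(x_km = 20, y_km = 20), years = 3,
                 n_replicates = 1, dem = demography_params(R_A = 3),
                 disp = dispersal_params(delta_km = 3),
                 master_seed = 9, track_positions = TRUE)
  tr <- run_invasion(sc)[[1]]
  d <- nest_density(tr, 3, g, cell_km = 1)
  expect_equal(sum(d$values) * 1^2, tr$counts[3])
  # two nests placed in one 1-km cell give 2 nests per km^2 there
  tr$positions[[2]] <- data.frame(x_km = c(10.2, 10.4), y_km = c(10.2, 10.3))
  tr$counts[2] <- 2L
  d2 <- nest_density(tr, 2, g, cell_km = 1)
  expect_equal(max(d2$values), 2)
  expect_equal(sum(d2$values > 0), 1)
})

test_that("wave speed is zero for a stationary population and needs 3 years", {
  tr <- structure(list(counts = rep(50L, 6), front_km = rep(12, 6)),
                  class = "invasion_trajectory")
  expect_equal(wave_speed(tr), 0)
  tr$counts <- c(50L, 50L, rep(1L, 4))
  expect_error(wave_speed(tr), "at least 3 years")
})

test_that("front speed increases with the dispersal scale", {
  # short, cheap runs: the ordering 14 vs 56 km is far outside noise
  slow <- front_speed_experiment(delta_km = 14, n_reps = 1, years = 8,
                                 grid = homogeneous_landscape(800),
                                 master_seed = 10)
  fast <- front_speed_experiment(delta_km = 56, n_reps = 1, years = 8,
                                 grid = homogeneous_landscape(1600),
                                 master_seed = 10)
  expect_gt(fast$mean_speed, slow$mean_speed)
})

test_that("dispersal calibration bisects to the target speed", {
  # deterministic monotone stand-in isolates the root-finding logic
  fake <- function(delta) 2.5 * delta
  res <- calibrate_delta(70, lo = 10, hi = 60, tol_km_yr = 1,
                         speed_fn = fake)
  expect_lt(abs(res$speed - 70), 1)
  expect_lt(abs(res$delta_km - 28), 0.5)
  expect_error(calibrate_delta(0, speed_fn = fake), "positive")
  expect_error(calibrate_delta(500, lo = 10, hi = 60, speed_fn = fake),
               "outside bracket")
  expect_error(calibrate_delta(50, lo = 10, hi = 60,
                               speed_fn = function(d) 100 - d),
               "not increasing")
})
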