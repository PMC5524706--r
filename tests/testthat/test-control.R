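test_that("certain detection destroys everything; zero detection is a no-op", {
  nests <- data.frame(id = 1:3, x_km = c(0, 5, 40), y_km = c(0, 0, 0),
                      year_founded = 1L, parent_id = NA_integer_,
                      status = "active")
  set.seed(41)
  all_found <- apply_control(nests, control_policy(p_detect = 1), 1)
  expect_true(all(all_found$status == "destroyed"))
  none <- apply_control(nests, control_policy(p_detect = 0), 1)
  expect_true(all(none$status == "active"))
  # before the start year the policy does nothing even with p_detect = 1
  late <- apply_control(nests, control_policy(1, start_year = 2), 1)
  expect_true(all(late$status == "active"))
})

test_that("radial searches respect the search geometry", {
  # A at the origin, B 5 km away (inside a 32-km search), C 40 km away
  # (outside any search). With p_detect = 0.5 and efficiency 1:
  #   P(B destroyed) = 0.5 + 0.5 * P(A primary) = 0.75
  #   P(C destroyed) = 0.5 (no search reaches it: 35 km from B, 40 from A)
  nests <- data.frame(id = 1:3, x_km = c(0, 5, 40), y_km = 0,
                      year_founded = 1L, parent_id = NA_integer_,
                      status = "active")
  pol <- control_policy(0.5, search_radius_km = 32, search_efficiency = 1)
  set.seed(42)
  n <- 4000
  hits <- matrix(FALSE, n, 3)
  for (i in seq_len(n))
    hits[i, ] <- apply_control(nests, pol, 1)$status == "destroyed"
  p <- colMeans(hits)
  expect_lt(abs(p[2] - 0.75), 3 * sqrt(0.75 * 0.25 / n))
  expect_lt(abs(p[3] - 0.50), 3 * sqrt(0.25 / n))
  # B at 5 km must be found whenever A is primary-detected
  expect_true(all(hits[hits[, 1] & !hits[, 2], 2] == TRUE) ||
              sum(hits[, 1] & !hits[, 2]) == 0)
})

test_that("zero efficiency or zero radius reduces to the pure detection model", {
  nests <- data.frame(id = 1:6, x_km = runif(6, 0, 10), y_km = runif(6, 0, 10),
                      year_founded = 1L, parent_id = NA_integer_,
                      status = "active")
  base <- hornetspread:::with_seed(43,
    apply_control(nests, control_policy(0.4), 1))
  no_eff <- hornetspread:::with_seed(43,
    apply_control(nests, control_policy(0.4, search_radius_km = 16,
                                        search_efficiency = 0), 1))
  no_rad <- hornetspread:::with_seed(43,
    apply_control(nests, control_policy(0.4, search_radius_km = 0,
                                        search_efficiency = 0.99), 1))
  expect_identical(base$status, no_eff$status)
  expect_identical(base$status, no_rad$status)
})

test_that("destroyed nests never reappear in later years", {
  g <- flat_grid()
  sc <- scenario(g, data.frame(x_km = 200, y_km = 200), years = 8,
                 n_replicates = 20, dem = demography_params(R_A = 2.5),
                 policy = control_policy(0.5), master_seed = 44)
  runs <- run_invasion(sc)
  for (tr in runs) {
    # counts are active nests at the start of each year; any destroyed
    # nest reduces the following year's parents, never later counts
    z <- which(tr$counts == 0)
    if (length(z) > 0) expect_true(all(tr$counts[z[1]:8] == 0))
  }
})

test_that("eradication probability is monotone in policy strength", {
  g <- flat_grid()
  dem <- demography_params(R_A = 3)
  sc <- scenario(g, data.frame(x_km = 200, y_km = 200), years = 15,
                 n_replicates = 150, dem = dem, master_seed = 45)
  # certain immediate detection always eradicates
  expect_equal(as.numeric(
    eradication_probability(sc, control_policy(1), n_reps = 20)), 1)

  ps <- c(0.3, 0.6, 0.9)
  erad <- sapply(ps, function(p)
    as.numeric(eradication_probability(sc, control_policy(p))))
  expect_true(all(diff(erad) > -0.08))  # non-decreasing up to MC noise
  # delayed start can only hurt
  e1 <- as.numeric(eradication_probability(sc, control_policy(0.8, 1)))
  e2 <- as.numeric(eradication_probability(sc, control_policy(0.8, 2)))
  expect_lte(e2, e1 + 0.08)
  # radial searching can only help
  e_r <- as.numeric(eradication_probability(
    sc, control_policy(0.6, search_radius_km = 32,
                       search_efficiency = 0.99)))
  e_0 <- as.numeric(eradication_probability(sc, control_policy(0.6)))
  expect_gte(e_r, e_0 - 0.08)
})

test_that("time to colonisation follows the geometric-thinning closed form", {
  g <- flat_grid(extent_km = 200)
  dem <- demography_params(R_A = 3)
  pol <- control_policy(0.6)
  sc <- scenario(g, data.frame(x_km = 100, y_km = 100), years = 12,
                 n_replicates = 400, dem = dem, master_seed = 46)
  e_hat <- as.numeric(eradication_probability(sc, pol))
  se_e <- attr(eradication_probability(sc, pol), "se")

  rate <- 2
  t_col <- time_to_colonisation(invasion_pressure(rate, window_years = 50),
                                pol, sc, n_reps = 300, master_seed = 47)
  expect_lt(t_col$censored_fraction, 0.05)
  pred <- 1 / (rate * (1 - e_hat))
  se_t <- sd(t_col$times, na.rm = TRUE) / sqrt(sum(!is.na(t_col$times)))
  # error in the estimated per-invasion eradication probability propagates
  # as d pred / d e = 1 / (r (1-e)^2)
  se_comb <- sqrt(se_t^2 + (se_e / (rate * (1 - e_hat)^2))^2)
  expect_lt(abs(t_col$mean_years - pred), 3 * se_comb)
})

test_that("perfect control or zero pressure give permanent exclusion", {
  g <- flat_grid(extent_km = 200)
  sc <- scenario(g, data.frame(x_km = 100, y_km = 100), years = 6,
                 n_replicates = 10, dem = demography_params(R_A = 3),
                 master_seed = 48)
  res <- time_to_colonisation(invasion_pressure(3, window_years = 10),
                              control_policy(1), sc, n_reps = 20,
                              master_seed = 49)
  expect_true(is.na(res$mean_years))
  expect_equal(res$censored_fraction, 1)
  res0 <- time_to_colonisation(invasion_pressure(0, window_years = 10),
                               control_policy(0.5), sc, n_reps = 5,
                               master_seed = 50)
  expect_equal(res0$censored_fraction, 1)
})
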