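# friction metric and diffusion profiles

test_that("force series validation enforces columns and uniform spacing", {
  expect_error(force_series(data.frame(t = 1:3)), "lacks columns")
  bad <- data.frame(walker = 1, t = c(1, 2, 4), force = 0, z_bin = 1,
                    lambda_index = 1)
  expect_error(force_series(bad), "not uniform")
})

test_that("the blocked autocovariance integral recovers the OU closed form", {
  tau_c <- 1; sig <- 3; dt <- 0.1
  fs <- ou_force_series(n = 2^19, dt = dt, sigma = sig, tau_c = tau_c,
                        seed = 42)
  fp <- accumulate_friction(fs, single_bin_grid(), n_blocks = 1024)
  I_est <- fp$g[1] / TH$beta^2
  expect_equal(I_est, sig^2 * tau_c, tolerance = 0.15)
  expect_false(fp$low_info[1])
})

test_that("white-noise forces collapse to the measurement floor and are flagged", {
  fs <- withr::with_seed(1, force_series(data.frame(
    walker = 1, t = (1:20000) * 0.1, force = rnorm(20000, 0, 2),
    z_bin = 1, lambda_index = 1)))
  fp <- accumulate_friction(fs, single_bin_grid(), n_blocks = 128)
  expect_true(fp$low_info[1])
  # the implied integral is at the single-sample floor, far below any
  # correlated signal: D enormous compared with a correlated series
  floor_g <- TH$beta^2 * 0.1 * var(fs$force) / 2
  expect_lt(fp$g[1], 3 * floor_g)
})

test_that("friction inverts to diffusion elementwise with missing-bin propagation", {
  fp <- tibble::tibble(walker = c(1, 1), z_bin = c(1, 2), z = c(0.1, 0.2),
                       g = c(2, NA), occupancy_ps = c(10, 0),
                       n_samples = c(100, 0), low_info = c(FALSE, NA))
  class(fp) <- c("friction_profile", class(fp))
  dp <- to_diffusion(fp)
  expect_equal(dp$D[1], 0.5)
  expect_true(is.na(dp$D[2]))
  # round trip: inverting the diffusion recovers the friction
  expect_equal(1 / dp$D[1], fp$g[1])
  fp$g[1] <- -1
  expect_error(to_diffusion(fp), "non-positive")
})

test_that("cross-walker combination averages friction and reports the spread", {
  mk <- function(w, g) {
    out <- tibble::tibble(walker = w, z_bin = 1:3, z = c(0.1, 0.2, 0.3),
                          g = g, occupancy_ps = 10, n_samples = 100,
                          low_info = FALSE)
    class(out) <- c("friction_profile", class(out))
    out
  }
  # identical walkers: SE identically 0
  dp0 <- combine_walkers(dplyr::bind_rows(mk(1, c(2, 4, 5)), mk(2, c(2, 4, 5))))
  expect_equal(dp0$se, rep(0, 3))
  expect_equal(dp0$D, 1 / c(2, 4, 5))

  # one walker missing a bin: value from the other, SE undefined there
  a <- mk(1, c(2, 4, 5)); b <- mk(2, c(3, NA, 6))
  dp1 <- combine_walkers(dplyr::bind_rows(a, b))
  expect_equal(dp1$D[2], 1 / 4)
  expect_true(is.na(dp1$se[2]))
  expect_identical(dp1$n_walkers[2], 1L)

  # known spread matches the direct SE formula on the diffusion scale
  gs <- list(c(2, 4, 5), c(2.5, 3.5, 5.5), c(1.8, 4.4, 4.6))
  dp2 <- combine_walkers(dplyr::bind_rows(purrr::imap(gs, ~mk(.y, .x))))
  gmat <- do.call(rbind, gs)
  expect_equal(dp2$D, 1 / colMeans(gmat))
  expect_equal(dp2$se, apply(1 / gmat, 2, sd) / sqrt(3))

  # grid mismatch across listed profiles
  cbad <- mk(2, c(3, 4, 6)); cbad$z_bin <- 4:6
  expect_error(combine_walkers(list(a, cbad)), "common grid")
})

test_that("the rolling median removes isolated spikes and preserves structure", {
  z <- seq(0, 1, by = 0.05)
  const <- diffusion_profile(z, rep(0.01, length(z)))
  expect_equal(rolling_median(const, 0.2)$D, const$D)

  spiked <- const
  spiked$D[10] <- 5
  expect_equal(rolling_median(spiked, 0.2)$D, const$D)

  mono <- diffusion_profile(z, 0.001 + z * 0.01)
  expect_true(all(diff(rolling_median(mono, 0.2)$D) >= 0))

  expect_error(rolling_median(const, 0.01), "grid spacing")
  expect_identical(attr(rolling_median(const, 0.2), "filter")$window_nm, 0.2)
})

test_that("the friction metric recovers free diffusion on a flat landscape", {
  land <- build_landscape(list(L = 0.4, solvent_level = 0, solvent_z = 0.2,
                               schedule = lambda_schedule(1)))
  grid <- awh_grid(0, 0.4, 0.01, 1)
  # overdamped fixture: gamma = 500/ps resolved by dt = 0.5 fs; slow MC
  # cadence so reference hops are rare on the force correlation time
  cfg <- suppressWarnings(awh_config(
    n_walkers = 2, force_constant = 25000, tau_t = 0.002, dt = 0.0005,
    mc_interval = 600, input_diffusion_spatial = 5e-3,
    input_diffusion_lambda = 5e-2, start_decoupled = FALSE))
  res <- run_awh(land, grid, cfg, 3e6, seed = 5, force_sample_interval = 4)
  fp <- accumulate_friction(res$force_series, grid, n_blocks = 128)
  dp <- rolling_median(combine_walkers(fp), 0.2)
  D_true <- TH$kT / (cfg$integrator$friction * cfg$integrator$mass)
  expect_equal(median(dp$D, na.rm = TRUE), D_true, tolerance = 0.25)
})

test_that("64 and 128 autocorrelation blocks agree on a long series", {
  fs <- ou_force_series(n = 2^18, dt = 0.1, sigma = 2, tau_c = 0.8, seed = 9)
  g64 <- accumulate_friction(fs, single_bin_grid(), n_blocks = 64)$g[1]
  g128 <- accumulate_friction(fs, single_bin_grid(), n_blocks = 128)$g[1]
  expect_equal(g64, g128, tolerance = 0.2)
})

test_that("estimated diffusion does not increase with simulation length on the gel toy", {
  land <- build_landscape(list(
    L = 1.2, solvent_level = -2, solvent_z = 1.05,
    theta = "trap",
    trap = list(center = 0.5, width = 0.3, depth = 4, barrier = 8),
    schedule = lambda_schedule(1)))
  grid <- awh_grid(0, 1.2, 0.01, 1)
  cfg <- suppressWarnings(awh_config(
    n_walkers = 2, force_constant = 25000, tau_t = 0.002, dt = 0.0005,
    mc_interval = 600, input_diffusion_spatial = 5e-3,
    input_diffusion_lambda = 5e-2, start_decoupled = FALSE))
  lengths_ps <- c(375, 750, 1500)
  med <- matrix(NA_real_, nrow = 3, ncol = length(lengths_ps))
  for (s in 1:3) {
    res <- run_awh(land, grid, cfg, 3e6, seed = 100 * s,
                   force_sample_interval = 4)
    for (i in seq_along(lengths_ps)) {
      sub <- dplyr::filter(res$force_series, t <= lengths_ps[i])
      fp <- accumulate_friction(force_series(sub), grid, n_blocks = 64)
      dp <- rolling_median(combine_walkers(fp), 0.2)
      med[s, i] <- median(dp$D, na.rm = TRUE)
    }
  }
  trend <- apply(med, 2, median)
  # tested as a median-over-seeds trend with a small noise allowance
  expect_true(all(diff(trend) <= 0.05 * trend[-length(trend)]))
})
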