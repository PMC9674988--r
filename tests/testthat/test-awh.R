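# AWH engine: bias initialization, target distributions, Monte Carlo moves,
# updates, covering/stage logic, determinism and PMF extraction

test_that("the initial histogram size shrinks when the initial error grows", {
  grid <- awh_grid(0, 2, 0.05, 5)
  n0 <- vapply(c(5, 10, 20, 40), function(e) {
    init_bias(grid, awh_config(initial_error = e, n_walkers = 2))$N0
  }, numeric(1))
  expect_true(all(diff(n0) < 0))
  # doubling the error divides N0 by 4 under the quadratic rule
  expect_equal(n0[1] / n0[2], 4, tolerance = 1e-12)
})

test_that("run metadata reports a ~1 ns alchemical crossing time at the solvation input diffusion", {
  grid <- awh_grid(0.5, 0.5, n_lambda = 21)
  cfg <- awh_config(input_diffusion_lambda = 1e-3, n_walkers = 16)
  b <- init_bias(grid, cfg)
  expect_equal(b$metadata$expected_crossing_lambda_ns, 1, tolerance = 1e-12)
})

test_that("target distributions normalize and weight the alchemical end states", {
  grid <- awh_grid(0, 2, 0.05, 21)
  tu <- make_target(grid, "uniform")
  expect_equal(sum(tu), 1, tolerance = 1e-12)
  expect_true(all(abs(tu - 1 / grid$n_points) < 1e-15))

  te <- make_target(grid, "end-state-weighted")
  expect_equal(sum(te), 1, tolerance = 1e-12)
  w <- te[1, ]  # lambda weights (spatially uniform)
  expect_true(all(w[1] > w[2:20]))
  expect_gte(w[1], w[21])
  expect_gt(w[21], w[2])

  expect_error(make_target(grid, c(rep(1, 20), -1)), ">= 0")
  expect_error(make_target(grid, rep(0, 21)), "zero")
})

test_that("a target confined to the coupled state degenerates to 1D sampling", {
  land <- single_barrier_landscape(n_lambda = 3)
  grid <- awh_grid(0, 2, 0.05, 3)
  cfg <- desk_awh_config(n_walkers = 2, start_decoupled = FALSE)
  tgt <- make_target(grid, c(1, 0, 0))
  res <- run_awh(land, grid, cfg, 2e4, seed = 2, target = tgt,
                 force_sample_interval = 0)
  expect_gt(sum(res$bias$visit_weights[, 1]), 0)
  expect_equal(sum(res$bias$visit_weights[, 2:3]), 0)
})

test_that("the umbrella bias force is harmonic in the displacement", {
  expect_identical(bias_force(1.0, 1.0), 0)
  expect_equal(bias_force(1.01, 1.0, 25000), -250)
  expect_equal(bias_force(0.99, 1.0, 25000), 250)
  cfg <- awh_config(n_walkers = 1)
  expect_equal(bias_force(1.01, 1.0, cfg), -250)
})

test_that("Gibbs resampling keeps a single-point reference and obeys dominance", {
  cfg <- desk_awh_config(n_walkers = 1)
  land <- flat_landscape(n_lambda = 1)
  # single grid point: reference cannot move
  g1 <- awh_grid(1, 1, n_lambda = 1)
  b1 <- manual_bias(g1, cfg)
  w <- list(z = 1.0, theta = 0, lambda_ref = 1)
  w2 <- mc_resample_reference(w, b1, land, cfg, seed = 3)
  expect_identical(w2$z_bin, 1L)
  expect_identical(w2$lambda_ref, 1L)
  # walker frozen far from all but one bin: that bin dominates
  g <- awh_grid(0, 2, 0.25, 1)
  b <- manual_bias(g, cfg)
  w <- list(z = 0.75, theta = 0, lambda_ref = 1)
  picks <- vapply(1:50, function(s) {
    mc_resample_reference(w, b, land, cfg, seed = s)$z_bin
  }, integer(1))
  expect_true(all(picks == 4L))  # bin at z = 0.75
})

test_that("bias updates vanish at the target, push down oversampled points, and grow N in the final stage", {
  cfg <- awh_config(n_walkers = 2, samples_per_update = 10)
  grid <- awh_grid(0, 2, 0.25, 2)
  b <- init_bias(grid, cfg, target = make_target(grid, "uniform"))

  # batch distributed exactly as the target: f unchanged (anchor included)
  batch <- matrix(rep(as.numeric(b$target), 10), nrow = 10, byrow = TRUE)
  b2 <- update_free_energy(b, batch)
  expect_equal(as.numeric(b2$f), rep(0, grid$n_points), tolerance = 1e-12)

  # all weight on point A: f(A) drops relative to f(B)
  gA <- awh_grid(0, 1.75, 0.25, 1)
  bA <- init_bias(gA, cfg, target = make_target(gA, "uniform"))
  dW <- c(10, rep(0, 7))
  attr(dW, "n_samples") <- 10
  bA2 <- update_free_energy(bA, dW)
  expect_lt(bA2$f[1, 1] - bA2$f[2, 1], 0)
  expect_equal(min(bA2$f), 0)  # anchored

  # NaN weights abort
  bad <- rep(NaN, grid$n_points)
  attr(bad, "n_samples") <- 10
  expect_error(update_free_energy(b, bad), "NaN")

  # N grows by the batch size per update only in the final stage
  expect_equal(b2$N, b$N)
  b$stage <- "final"
  b3 <- update_free_energy(b, batch)
  expect_equal(b3$N, b$N + 10)
})

test_that("covering requires per-walker lambda traversal and spatial diameter", {
  grid <- awh_grid(0, 2, 0.25, 2)
  cfg <- awh_config(n_walkers = 3, covering_min_diameter = 0.8)
  b <- init_bias(grid, cfg, target = make_target(grid, "uniform"))
  all_pts <- rep(TRUE, grid$n_points)
  full_lam <- rep(TRUE, 2)

  # one walker visited everything
  w_all <- list(lambda_visited = full_lam, z_range = c(0, 2),
                points_visited = all_pts)
  expect_true(covering_check(b, list(w_all), cfg))

  # collectively complete, but every walker's spatial diameter < 0.8 nm
  half1 <- seq_len(grid$n_points) <= 9 | (seq_len(grid$n_points) > 9 &
                                          seq_len(grid$n_points) <= 13)
  w1 <- list(lambda_visited = full_lam, z_range = c(0, 0.5),
             points_visited = half1)
  w2 <- list(lambda_visited = full_lam, z_range = c(1.25, 1.75),
             points_visited = !half1)
  expect_false(covering_check(b, list(w1, w2), cfg))

  # lambda incomplete for all walkers with the flag on
  w3 <- list(lambda_visited = c(TRUE, FALSE), z_range = c(0, 2),
             points_visited = all_pts)
  expect_false(covering_check(b, list(w3), cfg))
  cfg_off <- awh_config(n_walkers = 3, covering_requires_full_lambda = FALSE)
  expect_true(covering_check(b, list(w3), cfg_off))
})

test_that("stage advancement multiplies N at coverings and exits once N reaches the sample count", {
  grid <- awh_grid(0, 2, 0.25, 2)
  cfg <- awh_config(n_walkers = 2, growth_factor = 3)
  b <- init_bias(grid, cfg, target = make_target(grid, "uniform"))
  b$total_samples <- b$N0 * 20

  # never covered: stays initial with N untouched
  b1 <- advance_stage(b, FALSE)
  expect_identical(b1$stage, "initial")
  expect_equal(b1$N, b$N0)

  # covered repeatedly: N strictly increasing until the stage turns final
  Ns <- b$N
  bi <- b
  while (bi$stage == "initial") {
    bi <- advance_stage(bi, TRUE)
    Ns <- c(Ns, bi$N)
  }
  expect_true(all(diff(Ns) > 0))
  expect_identical(bi$stage, "final")
  expect_identical(bi$covering_count, 3L)  # 3^3 * N0 >= 20 N0
})

test_that("identical seeds give bit-identical runs; one walker is a valid run", {
  land <- desk_membrane_landscape(n_lambda = 3)
  grid <- awh_grid(0, land$L, 0.05, 3)
  cfg <- desk_awh_config(n_walkers = 2)
  r1 <- run_awh(land, grid, cfg, 3e4, seeds = c(11, 12))
  r2 <- run_awh(land, grid, cfg, 3e4, seeds = c(11, 12))
  expect_identical(r1$bias$f, r2$bias$f)
  expect_identical(r1$bias$N, r2$bias$N)
  expect_identical(r1$force_series$force, r2$force_series$force)
  expect_identical(r1$walkers, r2$walkers)

  r3 <- run_awh(land, grid, desk_awh_config(n_walkers = 1), 2e4, seeds = 5,
                force_sample_interval = 0)
  expect_s3_class(r3, "awh_result")
  expect_error(run_awh(land, grid, cfg, 1e3, seeds = c(4, 4)), "distinct")
})

test_that("PMF extraction slices, references and validates", {
  land <- flat_landscape(level = -2, n_lambda = 3)
  grid <- awh_grid(0, 2, 0.1, 3)
  cfg <- desk_awh_config(n_walkers = 2)
  res <- run_awh(land, grid, cfg, 4e5, seed = 9, force_sample_interval = 0)
  expect_error(extract_pmf(res, 7), "not in the grid")
  pmf <- extract_pmf(res, 1)
  expect_identical(attr(pmf, "reference_tag"), "vacuum")
  # flat landscape: PMF constant within noise, near the solvent level
  expect_lt(max(pmf$dG) - min(pmf$dG), 1)
  expect_equal(mean(pmf$dG), -2, tolerance = 0.15)
  # decoupled slice flat within noise
  dec <- extract_pmf(res, 3)
  expect_lt(max(dec$dG) - min(dec$dG), 1)
})

test_that("a run far too short to cover stays in the initial stage and warns at extraction", {
  land <- desk_membrane_landscape(n_lambda = 3)
  grid <- awh_grid(0, land$L, 0.05, 3)
  cfg <- desk_awh_config(n_walkers = 2)
  res <- run_awh(land, grid, cfg, 2e3, seed = 4, force_sample_interval = 0)
  expect_identical(res$bias$stage, "initial")
  expect_identical(res$bias$covering_count, 0L)
  expect_warning(extract_pmf(res, 1), "initial stage")
})

test_that("symmetrization mirror-averages, is idempotent and rejects non-uniform grids", {
  z <- seq(0, 1, by = 0.1)
  p <- pmf_profile(z, c(1, 2, 3, 4, 5, 6, 5, 4, 3, 2, 10))
  ps <- symmetrize(p)
  expect_equal(ps$dG[1], (1 + 10) / 2)
  expect_equal(ps$dG, rev(ps$dG))
  # already symmetric: unchanged
  expect_equal(symmetrize(ps)$dG, ps$dG)
  # idempotence on pseudo-random profiles
  for (s in 1:5) {
    vals <- sin(s * z * 7) + s * z
    pr <- pmf_profile(z, vals)
    expect_equal(symmetrize(symmetrize(pr))$dG, symmetrize(pr)$dG,
                 tolerance = 1e-14)
  }
  bad <- pmf_profile(c(0, 0.1, 0.3), c(1, 2, 3))
  expect_error(symmetrize(bad), "symmetric")
})

test_that("grid validation enforces spacing, bin count and the lambda-only special case", {
  expect_error(awh_grid(0, 2, -0.1), "z_spacing")
  expect_error(awh_grid(0, 0.2, 0.05), "at least 8")
  expect_silent(g1 <- awh_grid(0.5, 0.5, n_lambda = 21))
  expect_identical(g1$n_z, 1L)
  expect_identical(g1$n_points, 21L)
  g <- awh_grid(0, 2, 0.05, 21)
  expect_identical(g$n_points, g$n_z * g$n_lambda)
  expect_error(awh_grid(0, 2.013, 0.05), "multiple")
})

test_that("configuration validation flags non-positive fields and odd MC cadence", {
  expect_error(awh_config(initial_error = -1), "positive")
  expect_error(awh_config(force_constant = 0), "positive")
  expect_warning(awh_config(mc_interval = 37), "standard")
  cfg <- awh_config()
  expect_equal(cfg$initial_error, 10)
  expect_equal(cfg$input_diffusion_spatial, 3e-5)
  expect_equal(cfg$input_diffusion_lambda, 5e-5)
  expect_equal(cfg$force_constant, 25000)
  expect_identical(cfg$mc_interval, 10L)
  expect_identical(cfg$samples_per_update, 10L)
  expect_equal(cfg$covering_min_diameter, 0.8)
  expect_identical(cfg$n_walkers, 24L)
})
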