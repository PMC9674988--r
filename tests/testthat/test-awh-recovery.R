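# sampling properties of the adaptive-bias engine: free-energy recovery
# against quadrature oracles, flattening, and Gibbs stationarity

test_that("the adaptive bias recovers the two-state free-energy difference", {
  land <- two_state_landscape()
  ref <- reference_solvation(land)
  cfg <- awh_config(n_walkers = 4, input_diffusion_lambda = 1e-3,
                    force_constant = 1000)
  run <- run_solvation(land, cfg, n_steps = 2e5, seed = 11)
  expect_true(run$converged)
  expect_lt(abs(run$dG_solv - ref), 0.3)
})

test_that("the sampled multi-well PMF matches the quadrature reference", {
  land <- desk_membrane_landscape()
  grid <- awh_grid(0, land$L, 0.02, land$schedule$n_states)
  cfg <- desk_awh_config(n_walkers = 4)
  res <- run_awh(land, grid, cfg, 1e6, seed = 3, force_sample_interval = 0)
  expect_identical(res$bias$stage, "final")

  pmf <- extract_pmf(res, 1)
  ref <- reference_pmf(land, 1, z = grid$z, anchor = "vacuum")
  expect_lt(sqrt(mean((pmf$dG - ref$dG)^2)), 0.5)

  # at the umbrella resolution: compare against the kernel-convolved
  # reference, where the residual is purely statistical
  fconv <- convolved_reference(land, grid, cfg$force_constant)
  est <- res$bias$f - mean(res$bias$f[, grid$n_lambda])
  orc <- fconv - mean(fconv[, grid$n_lambda])
  expect_lt(sqrt(mean((est[, 1] - orc[, 1])^2)), 0.3)

  # barrier heights relative to the solvent plateau, against quadrature
  for (zb in c(0.7, 1.5)) {
    j <- which.min(abs(grid$z - zb))
    js <- which.min(abs(grid$z - land$solvent_z))
    expect_lt(abs((pmf$dG[j] - pmf$dG[js]) - (ref$dG[j] - ref$dG[js])), 0.3)
  }

  # solvation consistency: lambda free-energy difference on the plateau
  expect_lt(abs(solvation_free_energy(res) - reference_solvation(land)), 0.3)

  # the decoupled slice is flat within noise
  dec <- res$bias$f[, grid$n_lambda]
  expect_lt(sd(dec), 0.3)
})

test_that("a converged uniform-target bias flattens the sampled marginal", {
  land <- desk_membrane_landscape(n_lambda = 3)
  grid <- awh_grid(0, land$L, 0.1, 3)
  cfg <- desk_awh_config(n_walkers = 4, target_lambda = "uniform")
  learn <- run_awh(land, grid, cfg, 1e6, seed = 31,
                   force_sample_interval = 0)
  expect_identical(learn$bias$stage, "final")
  # frozen continuation at the learned bias: thinned reference-point visits
  # should be uniform over all grid points (chi-square, alpha = 0.01)
  probe <- run_awh(land, grid, cfg, 1.5e6, seed = 77, freeze_bias = TRUE,
                   f_init = learn$bias$f, force_sample_interval = 0,
                   traj_interval = 5000)
  lev <- as.vector(outer(seq_len(grid$n_z), seq_len(grid$n_lambda), paste))
  counts <- table(factor(paste(probe$traj$z_bin, probe$traj$lambda_index),
                         levels = lev))
  chi <- suppressWarnings(chisq.test(as.vector(counts)))
  expect_gt(chi$p.value, 0.01)
})

test_that("Gibbs reference moves are stationary under an exact bias", {
  land <- build_landscape(list(
    L = 0.8, solvent_level = 0, solvent_z = 0.7,
    barriers = data.frame(center = 0.4, height = 2, width = 0.12),
    schedule = lambda_schedule(3)))
  grid <- awh_grid(0, 0.8, 0.1, 3)
  cfg <- desk_awh_config(n_walkers = 4, target_lambda = "uniform")
  fexact <- convolved_reference(land, grid, cfg$force_constant,
                                dz_quad = 0.001)
  res <- run_awh(land, grid, cfg, 2e6, seed = 21, freeze_bias = TRUE,
                 f_init = fexact, force_sample_interval = 0,
                 traj_interval = 5000)
  lev <- as.vector(outer(1:9, 1:3, paste))
  counts <- table(factor(paste(res$traj$z_bin, res$traj$lambda_index),
                         levels = lev))
  chi <- suppressWarnings(chisq.test(as.vector(counts)))
  expect_gt(chi$p.value, 0.01)
})

test_that("two-dimensional sampling beats spatial-only sampling on the gel trap", {
  tab <- demo_convergence(n_steps = 2e5, seeds = 1:5, z_spacing = 0.02)
  wide <- tidyr::pivot_wider(tab, id_cols = "seed", names_from = "method",
                             values_from = "rmsd")
  expect_identical(nrow(wide), 5L)
  med <- tapply(tab$rmsd, tab$method, median)
  expect_lt(med[["2D"]], med[["1D"]])
  # one-sided sign test at alpha = 0.05
  wins <- sum(wide$`2D` < wide$`1D`)
  p <- binom.test(wins, nrow(wide), alternative = "greater")$p.value
  expect_lt(p, 0.05)
})

test_that("sampled PMF plus estimated diffusion reproduce the analytic permeability", {
  # one simulation serves both estimators: stiff umbrella and slow MC
  # cadence for the friction metric, an alchemical axis for calibration
  land <- build_landscape(list(
    L = 1.6, solvent_level = -3, solvent_z = 1.45,
    barriers = data.frame(center = 0.5, height = 6, width = 0.15),
    wells = data.frame(center = 0.9, depth = 3, width = 0.12),
    schedule = lambda_schedule(5)))
  grid <- awh_grid(0, 1.6, 0.01, 5)
  cfg <- suppressWarnings(awh_config(
    n_walkers = 4, force_constant = 25000, tau_t = 0.002, dt = 0.0005,
    mc_interval = 200, input_diffusion_spatial = 2e-3,
    input_diffusion_lambda = 5e-2))
  res <- run_awh(land, grid, cfg, 1.2e7, seed = 17,
                 force_sample_interval = 16)
  expect_identical(res$bias$stage, "final")

  pmf <- extract_pmf(res, 1)
  t_exit <- res$metadata$stage_exit_step * cfg$integrator$dt
  fp <- accumulate_friction(res$force_series, grid, n_blocks = 128,
                            t_min = t_exit)
  dp <- rolling_median(combine_walkers(fp), 0.2)
  est <- permeability_pipeline(pmf, dp, lm = layer_model(),
                               dG_solv = solvation_free_energy(res),
                               n_edge = 2)

  D_true <- TH$kT / (cfg$integrator$friction * cfg$integrator$mass)
  ana <- permeability_pipeline(
    reference_pmf(land, 1, z = grid$z, anchor = "vacuum"),
    diffusion_profile(grid$z, rep(D_true, grid$n_z)),
    lm = layer_model(), dG_solv = reference_solvation(land), n_edge = 0)
  expect_lt(abs(est$log10_KP - ana$log10_KP), 0.3)
})
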