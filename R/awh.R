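#' Reaction-coordinate grid for AWH sampling
#'
#' Defines the discretized reaction-coordinate space: spatial bins along z
#' times alchemical lambda states. A degenerate spatial axis (`n_z = 1`) gives
#' the lambda-only grid used for solvation free-energy runs; otherwise at
#' least 8 spatial bins are required.
#'
#' @param z_min,z_max Spatial extent in nm.
#' @param z_spacing Spatial bin spacing in nm.
#' @param n_lambda Number of lambda states (1 for spatial-only sampling).
#' @return An `awh_grid` object with bin centers `z` and point count
#'   `n_points = n_z * n_lambda`. Point index `(j, l)` is stored
#'   column-major: `m = (l - 1) * n_z + j`.
#' @export
awh_grid <- function(z_min = 0, z_max, z_spacing = 0.05, n_lambda = 21) {
  if (!is.finite(z_spacing) || z_spacing <= 0) {
    abort_validation("`z_spacing` must be > 0")
  }
  if (n_lambda < 1 || n_lambda != round(n_lambda)) {
    abort_validation("`n_lambda` must be a positive integer")
  }
  if (z_max < z_min) abort_validation("`z_max` must be >= `z_min`")
  if (z_max == z_min) {
    n_z <- 1L
  } else {
    n_z <- round((z_max - z_min) / z_spacing) + 1L
    if (abs((n_z - 1L) * z_spacing - (z_max - z_min)) > 1e-9) {
      abort_validation("grid extent must be an integer multiple of `z_spacing`")
    }
    if (n_z < 8L) {
      abort_validation("spatial grids need at least 8 bins (or exactly 1)")
    }
  }
  structure(
    list(z_min = z_min, z_max = z_max, z_spacing = z_spacing,
         n_z = as.integer(n_z), n_lambda = as.integer(n_lambda),
         n_points = as.integer(n_z * n_lambda),
         z = z_min + (seq_len(n_z) - 1L) * z_spacing),
    class = "awh_grid"
  )
}

#' @export
print.awh_grid <- function(x, ...) {
  cat(sprintf("<awh_grid> %d z-bin(s) x %d lambda state(s) = %d points, z in [%g, %g] nm, spacing %g nm\n",
              x$n_z, x$n_lambda, x$n_points, x$z_min, x$z_max, x$z_spacing))
  invisible(x)
}

#' AWH sampler configuration
#'
#' All tunable parameters of the accelerated weight histogram sampler. The
#' defaults are the production settings for membrane permeability runs:
#' initial error 10 kJ/mol, input diffusion constants 3e-5 nm^2/ps (spatial)
#' and 5e-5 1/ps (alchemical; 1e-3 1/ps for solvation-only runs), umbrella
#' force constant 25,000 kJ/mol/nm^2, Monte Carlo coordinate sampling every
#' 10 integration steps, 10 samples per bias update, and a covering rule
#' requiring each contributing walker to have spanned the full alchemical
#' dimension and a spatial diameter of at least 0.8 nm.
#'
#' The input diffusion constants only set the initial histogram size (through
#' the expected crossing time of the reaction coordinate); they do not enter
#' the diffusion profile computed from the friction metric.
#'
#' @param initial_error Rough estimate of the initial free-energy error,
#'   kJ/mol (default 10). Larger values give a smaller initial histogram and
#'   hence larger first updates.
#' @param input_diffusion_spatial Estimated diffusion constant along z,
#'   nm^2/ps (default 3e-5).
#' @param input_diffusion_lambda Estimated diffusion constant along the
#'   alchemical axis (lambda in `[0,1]`), 1/ps (default 5e-5; use 1e-3 for
#'   solvation-only runs).
#' @param force_constant Umbrella force constant, kJ/mol/nm^2 (default
#'   25,000); also sets the spatial resolution of the reaction coordinate.
#' @param mc_interval Integrator steps between Monte Carlo coordinate
#'   samplings (default 10; 100 is the other standard choice, anything else
#'   draws a warning).
#' @param samples_per_update Samples per update of the f-lambda bias
#'   (default 10).
#' @param covering_min_diameter Minimum spatial diameter (nm) a walker must
#'   have visited to count toward covering (default 0.8).
#' @param covering_requires_full_lambda Whether a walker must have visited
#'   every lambda state to count toward covering (default TRUE).
#' @param n_walkers Number of communicating walkers (default 24 for 2D runs;
#'   solvation runs use 16).
#' @param symmetrize Whether PMF extraction symmetrizes about the grid
#'   center by default.
#' @param target_lambda Target distribution along lambda:
#'   `"end-state-weighted"` (default), `"uniform"`, or a numeric weight
#'   vector. See [make_target()].
#' @param growth_factor Initial-stage histogram growth factor applied at
#'   each covering event (default 3).
#' @param dt,tau_t,mass,temperature Integrator parameters, see
#'   [integrator_params()].
#' @param start_decoupled Insert walkers at random positions with
#'   interactions turned off (default TRUE; ignored for spatial-only grids).
#' @return An `awh_config` object.
#' @export
awh_config <- function(initial_error = 10,
                       input_diffusion_spatial = 3e-5,
                       input_diffusion_lambda = 5e-5,
                       force_constant = 25000,
                       mc_interval = 10,
                       samples_per_update = 10,
                       covering_min_diameter = 0.8,
                       covering_requires_full_lambda = TRUE,
                       n_walkers = 24,
                       symmetrize = FALSE,
                       target_lambda = "end-state-weighted",
                       growth_factor = 3,
                       dt = 0.003, tau_t = 2, mass = 1,
                       temperature = 305.15,
                       start_decoupled = TRUE) {
  num <- c(initial_error = initial_error,
           input_diffusion_spatial = input_diffusion_spatial,
           input_diffusion_lambda = input_diffusion_lambda,
           force_constant = force_constant, mc_interval = mc_interval,
           samples_per_update = samples_per_update,
           covering_min_diameter = covering_min_diameter,
           n_walkers = n_walkers, growth_factor = growth_factor,
           dt = dt, tau_t = tau_t, mass = mass, temperature = temperature)
  bad <- names(num)[!is.finite(num) | num <= 0]
  if (length(bad)) {
    abort_validation(paste0("awh_config fields must be positive and finite: ",
                            paste(bad, collapse = ", ")))
  }
  if (!mc_interval %in% c(10, 100)) {
    warn("`mc_interval` outside the standard {10, 100}; proceeding")
  }
  ip <- integrator_params(dt = dt, tau_t = tau_t, mass = mass,
                          temperature = temperature)
  structure(
    list(initial_error = initial_error,
         input_diffusion_spatial = input_diffusion_spatial,
         input_diffusion_lambda = input_diffusion_lambda,
         force_constant = force_constant,
         mc_interval = as.integer(mc_interval),
         samples_per_update = as.integer(samples_per_update),
         covering_min_diameter = covering_min_diameter,
         covering_requires_full_lambda = isTRUE(covering_requires_full_lambda),
         n_walkers = as.integer(n_walkers),
         symmetrize = isTRUE(symmetrize),
         target_lambda = target_lambda,
         growth_factor = growth_factor,
         integrator = ip,
         start_decoupled = isTRUE(start_decoupled)),
    class = "awh_config"
  )
}

#' Target distribution over the reaction-coordinate grid
#'
#' Normalized product distribution: uniform along the spatial dimension times
#' a lambda weighting. The `"end-state-weighted"` choice puts extra weight on
#' the alchemical end states - most on the fully interacting state, then the
#' fully decoupled state - because the free-energy difference between the end
#' states is the quantity of interest; interior states only carry the
#' transformation path.
#'
#' @param grid An [awh_grid()].
#' @param lambda_weights `"uniform"`, `"end-state-weighted"`, or a numeric
#'   vector of non-negative weights (length `n_lambda`, not all zero).
#' @param spatial Only `"uniform"` is supported.
#' @return A `n_z x n_lambda` matrix summing to 1.
#' @export
make_target <- function(grid, lambda_weights = "end-state-weighted",
                        spatial = "uniform") {
  stopifnot(inherits(grid, "awh_grid"))
  if (!identical(spatial, "uniform")) {
    abort_validation('only spatial = "uniform" targets are supported')
  }
  nl <- grid$n_lambda
  if (is.character(lambda_weights)) {
    w <- switch(lambda_weights,
      "uniform" = rep(1, nl),
      "end-state-weighted" = {
        w <- rep(1, nl)
        if (nl > 1) { w[1] <- 4; w[nl] <- 2 }
        w
      },
      abort_validation(sprintf("unknown lambda weighting '%s'", lambda_weights))
    )
  } else {
    w <- as.numeric(lambda_weights)
    if (length(w) != nl) {
      abort_validation("lambda weight vector must have length n_lambda")
    }
    if (any(!is.finite(w)) || any(w < 0)) {
      abort_validation("lambda weights must be finite and >= 0")
    }
    if (sum(w) <= 0) abort_validation("lambda weights must not all be zero")
  }
  tgt <- matrix(rep(w, each = grid$n_z), nrow = grid$n_z, ncol = nl)
  tgt / sum(tgt)
}

#' Initialize the adaptive bias state
#'
#' The free-energy estimate starts at zero and the initial reference
#' weight-histogram size is set indirectly from the estimated initial error
#' and the input diffusion constants:
#' `N0 = (kT / initial_error)^2 * tau_cross / dt_sample`, where `tau_cross =
#' max(extent_z^2 / D_z, 1 / D_lambda)` is the expected time to cross the
#' slowest reaction-coordinate dimension and `dt_sample` the time between
#' coordinate samples. The rule is monotone: a larger initial error gives a
#' smaller `N0` and therefore larger first updates.
#'
#' @param grid An [awh_grid()].
#' @param cfg An [awh_config()].
#' @param target Optional target matrix; defaults to
#'   `make_target(grid, cfg$target_lambda)`.
#' @return An `awh_bias` object: free energy `f` (n_z x n_lambda, kJ/mol),
#'   `target`, histogram size `N`, `stage` (`"initial"`), accumulated
#'   `visit_weights`, `covering_count`, and run metadata including the
#'   expected crossing times in ps.
#' @export
init_bias <- function(grid, cfg = awh_config(), target = NULL) {
  stopifnot(inherits(grid, "awh_grid"), inherits(cfg, "awh_config"))
  if (grid$n_points < 2) abort_validation("degenerate grid: fewer than 2 points")
  if (is.null(target)) target <- make_target(grid, cfg$target_lambda)
  if (abs(sum(target) - 1) > 1e-12) {
    abort_validation("target distribution must sum to 1")
  }
  kT <- cfg$integrator$kT
  tau_z <- if (grid$n_z > 1) {
    (grid$z_max - grid$z_min)^2 / cfg$input_diffusion_spatial
  } else 0
  tau_lambda <- if (grid$n_lambda > 1) 1 / cfg$input_diffusion_lambda else 0
  tau_cross <- max(tau_z, tau_lambda)
  if (tau_cross <= 0) abort_validation("grid has no sampled dimension")
  dt_sample <- cfg$mc_interval * cfg$integrator$dt
  N0 <- (kT / cfg$initial_error)^2 * tau_cross / dt_sample
  structure(
    list(f = matrix(0, grid$n_z, grid$n_lambda),
         target = target,
         N = N0, N0 = N0,
         stage = "initial",
         visit_weights = matrix(0, grid$n_z, grid$n_lambda),
         covering_count = 0L,
         total_samples = 0,
         grid = grid, cfg = cfg,
         metadata = list(
           expected_crossing_z_ps = tau_z,
           expected_crossing_lambda_ps = tau_lambda,
           expected_crossing_lambda_ns = tau_lambda / 1000
         )),
    class = "awh_bias"
  )
}

#' @export
print.awh_bias <- function(x, ...) {
  cat(sprintf("<awh_bias> %d points, stage %s, N = %.4g (N0 = %.4g), %d covering(s)\n",
              x$grid$n_points, x$stage, x$N, x$N0, x$covering_count))
  invisible(x)
}

#' Harmonic umbrella bias force
#'
#' The force the bias exerts on the walker through the harmonic umbrella
#' steering the permeant: `-k (z - z_ref)`.
#'
#' @param z Walker position, nm.
#' @param z_ref Reference point position, nm.
#' @param force_constant Umbrella force constant, kJ/mol/nm^2 (default
#'   25,000), or an [awh_config()].
#' @return Force in kJ/mol/nm.
#' @export
bias_force <- function(z, z_ref, force_constant = 25000) {
  if (inherits(force_constant, "awh_config")) {
    force_constant <- force_constant$force_constant
  }
  -force_constant * (z - z_ref)
}

# Gibbs window half-width in bins: 4 umbrella sigma, at least one bin
gibbs_window_bins <- function(grid, cfg) {
  if (grid$n_z == 1L) return(0L)
  sig <- sqrt(cfg$integrator$kT / cfg$force_constant)
  max(1L, as.integer(ceiling(4 * sig / grid$z_spacing)))
}

#' Monte Carlo resampling of the reference point
#'
#' Full Gibbs sweep over candidate reference points (all lambda states, and
#' spatial bins within 4 umbrella standard deviations of the walker, for
#' tractability), with stationary weight
#' `target(m) exp(beta f(m)) exp(-beta [k/2 (z - z_m)^2 + U(z, theta,
#' lambda_m) - U(z, theta, lambda_cur)])`. An accepted lambda move switches
#' the walker's governing Hamiltonian instantaneously.
#'
#' @param walker List with `z`, `theta`, `lambda_ref` (1-based index).
#' @param bias An [init_bias()] state.
#' @param landscape A `toy_landscape`.
#' @param cfg An [awh_config()].
#' @param seed Integer seed for this draw.
#' @return The walker with updated `z_ref`, `z_bin` and `lambda_ref`; the
#'   normalized Gibbs weights over grid points are attached as attribute
#'   `"weights"` (the sample weight vector used in bias updates).
#' @export
mc_resample_reference <- function(walker, bias, landscape, cfg = bias$cfg,
                                  seed = 1) {
  grid <- bias$grid
  res <- gibbs_move_cpp(unclass(landscape), unclass(grid),
                        as.numeric(bias$f), as.numeric(bias$target),
                        1 / cfg$integrator$kT, cfg$force_constant,
                        walker$z, walker$theta %||% 0,
                        as.integer(walker$lambda_ref) - 1L,
                        gibbs_window_bins(grid, cfg), as.double(seed))
  walker$z_bin <- res$z_bin
  walker$lambda_ref <- res$lambda_index
  walker$z_ref <- grid$z[res$z_bin]
  attr(walker, "weights") <- matrix(res$weights, grid$n_z, grid$n_lambda)
  walker
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Update the free-energy estimate from a sample batch
#'
#' Weighted-histogram update: with accumulated sample weights `dW(m)` from a
#' batch of `n` samples,
#' `f(m) <- f(m) - kT log[(N rho(m) + dW(m)) / (N rho(m) + n rho(m))]`,
#' followed by re-anchoring so the minimum of `f` over the target support is
#' 0. The expected update vanishes when the sampled marginal equals the
#' target, and the update magnitude scales as `1/N`. In the final stage `N`
#' grows by the batch size per update; in the initial stage `N` is controlled
#' by covering events (see [advance_stage()]).
#'
#' @param bias An `awh_bias`.
#' @param sample_batch Matrix of per-sample point-weight vectors (one row per
#'   sample, `n_points` columns, each row summing to 1), or a single
#'   accumulated weight vector with attribute `n_samples`.
#' @return The updated `awh_bias`.
#' @export
update_free_energy <- function(bias, sample_batch) {
  stopifnot(inherits(bias, "awh_bias"))
  if (is.matrix(sample_batch) && is.null(attr(sample_batch, "n_samples")) &&
      nrow(sample_batch) > 1 && ncol(sample_batch) == bias$grid$n_points) {
    dW <- colSums(sample_batch)
    n <- nrow(sample_batch)
  } else {
    dW <- as.numeric(sample_batch)
    n <- attr(sample_batch, "n_samples") %||% sum(dW)
  }
  if (length(dW) != bias$grid$n_points) {
    abort_validation("sample batch width must equal the number of grid points")
  }
  if (any(is.na(dW))) abort_numerical("NaN in sample weights")
  kT <- bias$cfg$integrator$kT
  res <- awh_update_cpp(as.numeric(bias$f), as.numeric(bias$target),
                        bias$N, dW, n, kT)
  bias$f <- matrix(res$f, bias$grid$n_z, bias$grid$n_lambda)
  bias$visit_weights <- bias$visit_weights +
    matrix(dW, bias$grid$n_z, bias$grid$n_lambda)
  bias$total_samples <- bias$total_samples + n
  if (bias$stage == "final") bias$N <- bias$N + n
  bias
}

#' Covering check for the initial stage
#'
#' TRUE iff the union of qualifying walkers covers every target-supported
#' grid point, where a walker qualifies only if (a) it has individually
#' visited the whole lambda range since the last covering (when
#' `covering_requires_full_lambda` is on) and (b) its visited spatial
#' diameter is at least `covering_min_diameter` (capped at the grid extent).
#'
#' @param bias An `awh_bias`.
#' @param walkers List of walker covering records, each with
#'   `lambda_visited` (logical, length `n_lambda`), `z_range`
#'   (`c(lo, hi)` nm) and `points_visited` (logical, length `n_points`).
#' @param cfg An [awh_config()].
#' @return Logical.
#' @export
covering_check <- function(bias, walkers, cfg = bias$cfg) {
  grid <- bias$grid
  required <- min(cfg$covering_min_diameter,
                  (grid$n_z - 1L) * grid$z_spacing)
  covered <- rep(FALSE, grid$n_points)
  for (w in walkers) {
    full_lambda <- !cfg$covering_requires_full_lambda ||
      grid$n_lambda == 1L || all(w$lambda_visited)
    diam <- diff(w$z_range)
    spatial_ok <- grid$n_z == 1L ||
      (is.finite(diam) && diam >= required - 1e-12)
    if (full_lambda && spatial_ok) covered <- covered | w$points_visited
  }
  all(covered[as.numeric(bias$target) > 0])
}

#' Advance the AWH stage after a covering check
#'
#' In the initial stage, each covering event multiplies the reference
#' histogram size by the growth factor and resets the walkers' covering
#' bookkeeping; the bias exits to the final stage once `N` reaches the number
#' of samples collected so far. In the final stage `N` grows linearly (one
#' count per sample) in [update_free_energy()]. A bias that is never covered
#' stays in the initial stage indefinitely.
#'
#' @param bias An `awh_bias`.
#' @param covered Result of [covering_check()].
#' @return The updated `awh_bias`.
#' @export
advance_stage <- function(bias, covered) {
  stopifnot(inherits(bias, "awh_bias"))
  if (bias$stage == "initial" && isTRUE(covered)) {
    bias$N <- bias$N * bias$cfg$growth_factor
    bias$covering_count <- bias$covering_count + 1L
    if (bias$N >= bias$total_samples) bias$stage <- "final"
  }
  bias
}

#' Run the accelerated weight histogram sampler
#'
#' Multi-walker AWH: all walkers alternate Langevin integration steps, Monte
#' Carlo reference-point moves and updates of the shared adaptive bias
#' ("communicating walkers"). The friction data (bias-force time series) are
#' kept per walker. Fully reproducible: all randomness flows through
#' per-walker streams keyed by `(seed, walker)`.
#'
#' @param landscape A `toy_landscape`.
#' @param grid An [awh_grid()].
#' @param cfg An [awh_config()]; `cfg$n_walkers` walkers are run unless
#'   `seeds` is given.
#' @param n_steps Integration steps per walker.
#' @param seeds Integer vector of distinct per-walker seeds (default
#'   `seed + 0:(n_walkers-1)`).
#' @param seed Base seed used when `seeds` is not supplied.
#' @param force_sample_interval Steps between bias-force samples for the
#'   friction metric (default: `cfg$mc_interval`); 0 disables recording.
#' @param traj_interval Steps between trajectory records (0 = off).
#' @param freeze_bias Keep the bias fixed at `f_init` (no updates, no stage
#'   logic); used for sampling diagnostics.
#' @param f_init Optional initial free-energy matrix (default all zero).
#' @param target Optional target matrix override.
#' @return An `awh_result` with elements `bias` (the final `awh_bias`),
#'   `walkers` (final states tibble), `force_series` (tibble: walker, t,
#'   force, z_bin, lambda_index), `traj` (tibble or NULL) and `metadata`
#'   (seeds, covering events, stage exit, sample counts, expected crossing
#'   times).
#' @export
run_awh <- function(landscape, grid, cfg = awh_config(), n_steps,
                    seeds = NULL, seed = 1,
                    force_sample_interval = NULL, traj_interval = 0,
                    freeze_bias = FALSE, f_init = NULL, target = NULL) {
  stopifnot(inherits(landscape, "toy_landscape"), inherits(grid, "awh_grid"),
            inherits(cfg, "awh_config"))
  if (grid$n_lambda != landscape$schedule$n_states) {
    abort_validation("grid n_lambda must match the landscape lambda schedule")
  }
  if (grid$z_min < -1e-9 || grid$z_max > landscape$L + 1e-9) {
    abort_validation("grid must lie within the landscape domain [0, L]")
  }
  if (is.null(seeds)) seeds <- seed + seq_len(cfg$n_walkers) - 1L
  if (anyDuplicated(seeds)) abort_validation("per-walker seeds must be distinct")
  bias0 <- init_bias(grid, cfg, target = target)
  if (is.null(f_init)) f_init <- bias0$f
  if (is.null(force_sample_interval)) force_sample_interval <- cfg$mc_interval

  ccfg <- list(kT = cfg$integrator$kT,
               force_constant = cfg$force_constant,
               mc_interval = cfg$mc_interval,
               samples_per_update = cfg$samples_per_update,
               covering_min_diameter = cfg$covering_min_diameter,
               covering_requires_full_lambda = cfg$covering_requires_full_lambda,
               growth_factor = cfg$growth_factor,
               N0 = bias0$N0,
               dt = cfg$integrator$dt,
               friction = cfg$integrator$friction,
               mass = cfg$integrator$mass,
               start_decoupled = cfg$start_decoupled)

  res <- run_awh_cpp(unclass(landscape), unclass(grid), ccfg,
                     as.integer(n_steps), as.numeric(seeds),
                     as.numeric(f_init), as.numeric(bias0$target),
                     isTRUE(freeze_bias),
                     as.integer(force_sample_interval),
                     as.integer(traj_interval))

  bias <- bias0
  bias$f <- res$f
  bias$N <- res$N
  bias$stage <- res$stage
  bias$visit_weights <- res$visit_weights
  bias$covering_count <- res$covering_count
  bias$total_samples <- res$total_samples

  fs <- NULL
  if (force_sample_interval > 0) {
    fs <- purrr::imap(res$force_series, function(m, i) {
      tibble(walker = i, t = m[, "t"], force = m[, "force"],
             z_bin = as.integer(m[, "z_bin"]),
             lambda_index = as.integer(m[, "lambda_index"]))
    })
    fs <- dplyr::bind_rows(fs)
  }
  traj <- NULL
  if (traj_interval > 0) {
    traj <- as_tibble(as.data.frame(res$traj))
    traj$walker <- as.integer(traj$walker)
    traj$z_bin <- as.integer(traj$z_bin)
    traj$lambda_index <- as.integer(traj$lambda_index)
  }

  structure(
    list(bias = bias, grid = grid, cfg = cfg, landscape = landscape,
         walkers = as_tibble(as.data.frame(res$walkers)),
         force_series = fs, traj = traj,
         metadata = list(
           seeds = seeds,
           n_steps_per_walker = n_steps,
           time_per_walker_ps = n_steps * cfg$integrator$dt,
           total_time_ps = n_steps * cfg$integrator$dt * length(seeds),
           covering_steps = res$covering_steps,
           covering_count = res$covering_count,
           stage_exit_step = if (res$stage_exit_step >= 0)
             res$stage_exit_step else NA_real_,
           total_samples = res$total_samples,
           n_updates = res$n_updates,
           N0 = res$N0, N = res$N,
           expected_crossing_z_ps = bias0$metadata$expected_crossing_z_ps,
           expected_crossing_lambda_ps =
             bias0$metadata$expected_crossing_lambda_ps,
           expected_crossing_lambda_ns =
             bias0$metadata$expected_crossing_lambda_ns,
           freeze_bias = isTRUE(freeze_bias))),
    class = "awh_result"
  )
}

#' @export
print.awh_result <- function(x, ...) {
  cat(sprintf(
    "<awh_result> %d walker(s) x %d steps (%.4g ns total), stage %s, %d covering(s), N = %.4g\n",
    length(x$metadata$seeds), x$metadata$n_steps_per_walker,
    x$metadata$total_time_ps / 1000, x$bias$stage,
    x$bias$covering_count, x$bias$N))
  invisible(x)
}

#' Extract a PMF slice from the adaptive bias
#'
#' One-dimensional slice of the free-energy estimate along z at a given
#' lambda state. The fully interacting slice (`lambda_index = 1`) is "the
#' PMF". For 2D grids the slice is referenced to the fully decoupled state
#' (vacuum calibration): `dG(z) = f(z, lambda) - mean(f(., lambda_last))`;
#' spatial-only grids are shifted so the minimum is 0 and tagged as
#' solvent-referenced (they carry no insertion information).
#'
#' @param x An `awh_result` or `awh_bias`.
#' @param lambda_index 1-based lambda state (default 1, fully interacting).
#' @param symmetrize Mirror-average about the grid center (default: the
#'   configuration's `symmetrize` flag).
#' @return A [pmf_profile()].
#' @export
extract_pmf <- function(x, lambda_index = 1, symmetrize = NULL) {
  bias <- if (inherits(x, "awh_result")) x$bias else x
  stopifnot(inherits(bias, "awh_bias"))
  grid <- bias$grid
  if (lambda_index < 1 || lambda_index > grid$n_lambda) {
    abort_validation("requested lambda state is not in the grid")
  }
  if (bias$stage == "initial") {
    warn("bias is still in the initial stage; the PMF may be far from converged")
  }
  f <- bias$f[, lambda_index]
  if (grid$n_lambda > 1) {
    dG <- f - mean(bias$f[, grid$n_lambda])
    tag <- "vacuum"
  } else {
    dG <- f - min(f)
    tag <- "solvent"
  }
  out <- pmf_profile(z = grid$z, dG = dG, reference = tag)
  do_sym <- symmetrize %||% (inherits(x, "awh_result") && x$cfg$symmetrize)
  if (isTRUE(do_sym)) out <- symmetrize(out)
  out
}

#' Solvation free energy estimated from a 2D bias
#'
#' Difference between the fully interacting and fully decoupled free-energy
#' levels on the solvent plateau: the bias-derived estimate of the solvation
#' (hydration-analog) free energy, in the insertion convention
#' (`dG = G_coupled - G_decoupled`; negative = favourable).
#'
#' @param x An `awh_result` or `awh_bias` on a grid with `n_lambda > 1`.
#' @param z_window Range of z (nm) treated as the solvent plateau; defaults
#'   to a window of 5% of the grid extent around the landscape's
#'   `solvent_z` (falling back to the upper grid edge).
#' @return Scalar free energy, kJ/mol.
#' @export
solvation_free_energy <- function(x, z_window = NULL) {
  bias <- if (inherits(x, "awh_result")) x$bias else x
  stopifnot(inherits(bias, "awh_bias"))
  grid <- bias$grid
  if (grid$n_lambda < 2) {
    abort_validation("solvation estimate requires an alchemical dimension")
  }
  if (is.null(z_window)) {
    zs <- if (inherits(x, "awh_result")) x$landscape$solvent_z else grid$z_max
    half <- max(0.05 * (grid$z_max - grid$z_min), grid$z_spacing)
    z_window <- c(zs - half, zs + half)
  }
  j <- which(grid$z >= z_window[1] - 1e-9 & grid$z <= z_window[2] + 1e-9)
  if (!length(j)) abort_validation("no grid bins inside the solvent window")
  mean(bias$f[j, 1] - bias$f[j, grid$n_lambda])
}

#' Mirror-symmetrize a profile about the grid center
#'
#' Averages mirror-paired bins on the free-energy scale; the operation is
#' idempotent and requires a grid symmetric about its center (uniform
#' spacing).
#'
#' @param x A [pmf_profile()] or an `awh_result` (whose whole bias matrix is
#'   mirrored).
#' @param mode Only `"mirror-about-center"`.
#' @return Same class as the input.
#' @export
symmetrize <- function(x, mode = "mirror-about-center") {
  if (!identical(mode, "mirror-about-center")) {
    abort_validation('only mode = "mirror-about-center" is supported')
  }
  UseMethod("symmetrize")
}

#' @export
symmetrize.pmf_profile <- function(x, mode = "mirror-about-center") {
  dz <- diff(x$z)
  if (length(dz) && (max(dz) - min(dz)) > 1e-9) {
    abort_validation("symmetrize requires a grid symmetric about its center")
  }
  x$dG <- (x$dG + rev(x$dG)) / 2
  if ("se" %in% names(x) && !all(is.na(x$se))) {
    x$se <- sqrt((x$se^2 + rev(x$se)^2)) / 2
  }
  x
}

#' @export
symmetrize.awh_result <- function(x, mode = "mirror-about-center") {
  x$bias$f <- (x$bias$f + x$bias$f[nrow(x$bias$f):1, , drop = FALSE]) / 2
  x
}
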