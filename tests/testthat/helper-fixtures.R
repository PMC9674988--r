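# shared fixtures and oracles for the test suite; everything is generated
# in code, nothing is stored on disk

TH <- thermo_params()

# isolated single-barrier landscape: barrier top energy is exactly
# solvent_level + height (no overlap between features)
single_barrier_landscape <- function(height = 10, n_lambda = 5) {
  build_landscape(list(
    L = 2, solvent_level = -4, solvent_z = 1.8,
    barriers = data.frame(center = 0.7, height = height, width = 0.12),
    schedule = lambda_schedule(n_lambda)
  ))
}

flat_landscape <- function(level = 0, n_lambda = 1, L = 2) {
  build_landscape(list(L = L, solvent_level = level, solvent_z = 0.9 * L,
                       schedule = lambda_schedule(n_lambda)))
}

two_well_landscape <- function(barrier = 3) {
  build_landscape(list(
    L = 1.6, solvent_level = 0, solvent_z = 1.5,
    barriers = data.frame(center = 0.8, height = barrier, width = 0.15),
    schedule = lambda_schedule(1)
  ))
}

# umbrella-convolved free energy on the grid points: what the sampler's
# reference-point free energy converges to at finite umbrella stiffness
# (boundary-folded Gaussian kernel, quadrature over z and theta)
convolved_reference <- function(landscape, grid, force_constant,
                                thermo = TH, dz_quad = 0.002,
                                n_theta = 64) {
  beta <- thermo$beta
  zf <- seq(0, landscape$L, by = dz_quad)
  nl <- grid$n_lambda
  has_theta <- landscape$theta_mode > 0L
  th_nodes <- if (has_theta) {
    seq(-pi, pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  } else 0
  f <- matrix(0, grid$n_z, nl)
  for (l in seq_len(nl)) {
    # Boltzmann weight integrated over theta at each z
    wz <- rowMeans(vapply(th_nodes, function(th)
      exp(-beta * potential(landscape, zf, th, l)), numeric(length(zf))))
    for (j in seq_len(grid$n_z)) {
      zm <- grid$z[j]
      kern <- exp(-beta * force_constant / 2 * (zf - zm)^2) +
              exp(-beta * force_constant / 2 * (zf + zm)^2) +
              exp(-beta * force_constant / 2 * (2 * landscape$L - zf - zm)^2)
      f[j, l] <- -thermo$kT * log(sum(wz * kern) * dz_quad)
    }
  }
  f
}

# seeded Ornstein-Uhlenbeck force series with known variance and
# correlation time; the autocovariance integral is sigma^2 * tau_c
ou_force_series <- function(n, dt, sigma, tau_c, seed = 42, walker = 1) {
  withr::with_seed(seed, {
    a <- exp(-dt / tau_c)
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sigma)
    eps <- rnorm(n - 1, 0, sigma * sqrt(1 - a^2))
    for (i in 2:n) x[i] <- a * x[i - 1] + eps[i - 1]
    force_series(data.frame(walker = walker, t = (1:n) * dt, force = x,
                            z_bin = 1, lambda_index = 1))
  })
}

single_bin_grid <- function(z = 0.5) awh_grid(z, z, n_lambda = 1)

# minimal hand-built bias object for operation-level tests that bypass
# init_bias's grid checks
manual_bias <- function(grid, cfg, f = NULL, target = NULL) {
  structure(
    list(f = f %||% matrix(0, grid$n_z, grid$n_lambda),
         target = target %||% matrix(1 / grid$n_points, grid$n_z,
                                     grid$n_lambda),
         N = 1000, N0 = 1000, stage = "initial",
         visit_weights = matrix(0, grid$n_z, grid$n_lambda),
         covering_count = 0L, total_samples = 0,
         grid = grid, cfg = cfg, metadata = list()),
    class = "awh_bias"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
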