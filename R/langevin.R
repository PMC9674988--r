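#' Stochastic dynamics integrator parameters
#'
#' Parameters of the velocity Langevin (BAOAB) integrator used by all toy
#' simulations. The friction constant is the inverse of the coupling time
#' constant, `friction = 1 / tau_t`.
#'
#' @param dt Time step in ps (default 0.003, i.e. a 3 fs step).
#' @param tau_t Friction coupling time constant in ps (default 2, i.e. a
#'   friction constant of 0.5 1/ps).
#' @param mass Particle mass in reduced units (kJ/mol ps^2/nm^2), default 1.
#' @param temperature Temperature in K (default 305.15).
#' @return An `integrator_params` object with fields `dt`, `tau_t`,
#'   `friction`, `mass`, `temperature`, `kT`.
#' @export
integrator_params <- function(dt = 0.003, tau_t = 2, mass = 1,
                              temperature = 305.15) {
  if (!is.finite(dt) || dt <= 0) abort_validation("`dt` must be > 0")
  if (!is.finite(tau_t) || tau_t <= 0) abort_validation("`tau_t` must be > 0")
  if (!is.finite(mass) || mass <= 0) abort_validation("`mass` must be > 0")
  th <- thermo_params(temperature)
  structure(
    list(dt = dt, tau_t = tau_t, friction = 1 / tau_t, mass = mass,
         temperature = temperature, kT = th$kT),
    class = "integrator_params"
  )
}

#' Run unbiased or umbrella-restrained Langevin dynamics
#'
#' Integrates a single walker on a toy landscape at a fixed lambda state with
#' the BAOAB velocity Langevin scheme. The fluctuation-dissipation theorem is
#' satisfied exactly in the Ornstein-Uhlenbeck substep, so the stationary
#' kinetic energy is `kT/2` per degree of freedom. Optionally an umbrella
#' restraint `-k (z - z_ref)` and/or a constant external force can be applied.
#'
#' @param landscape A `toy_landscape`.
#' @param n_steps Number of integration steps.
#' @param params An [integrator_params()].
#' @param seed Integer seed for the walker's private random stream.
#' @param lambda_index 1-based lambda state (default 1, fully coupled).
#' @param z0,v0,theta0,vtheta0 Initial conditions; `v0`/`vtheta0` default to
#'   `NULL`, meaning Maxwell-Boltzmann draws.
#' @param record_every Record the state every this many steps.
#' @param umbrella Optional list `(force_constant, z_ref)`.
#' @param f_ext Constant external force on z, kJ/mol/nm (default 0).
#' @return A tibble with columns `t` (ps), `z`, `v`, `theta`, `vtheta`.
#' @export
run_langevin <- function(landscape, n_steps, params = integrator_params(),
                         seed = 1, lambda_index = 1, z0 = landscape$L / 2,
                         v0 = NULL, theta0 = 0, vtheta0 = NULL,
                         record_every = 1, umbrella = NULL, f_ext = 0) {
  stopifnot(inherits(landscape, "toy_landscape"))
  n_lam <- landscape$schedule$n_states
  if (lambda_index < 1 || lambda_index > n_lam) {
    abort_validation(sprintf("lambda_index must be in 1..%d", n_lam))
  }
  sv <- sqrt(params$kT / params$mass)
  # deterministic fallback draws so the C++ stream is the only RNG consumer
  if (is.null(v0)) v0 <- sv * init_normal(seed, 1L)
  if (is.null(vtheta0)) vtheta0 <- sv * init_normal(seed, 2L)
  k_umb <- 0; z_ref <- 0
  if (!is.null(umbrella)) {
    k_umb <- umbrella$force_constant
    z_ref <- umbrella$z_ref
  }
  m <- langevin_run_cpp(unclass(landscape), as.integer(lambda_index) - 1L,
                        as.integer(n_steps), params$dt, params$friction,
                        params$mass, params$kT, as.double(seed),
                        z0, v0, theta0, vtheta0,
                        as.integer(record_every), k_umb, z_ref, f_ext)
  as_tibble(as.data.frame(m))
}

# small deterministic normal for initial velocities, independent of R's RNG
init_normal <- function(seed, k) {
  u1 <- ((seed * 2654435761 + k * 40503) %% 2147483647 + 0.5) / 2147483647
  u2 <- ((seed * 22695477 + k * 65537) %% 2147483647 + 0.5) / 2147483647
  sqrt(-2 * log(u1)) * cos(2 * pi * u2)
}

#' Advance a walker by one Langevin step
#'
#' Single-step form of [run_langevin()] for a walker state carrying its own
#' coordinates; the bias force is passed explicitly as a constant over the
#' step (the harmonic umbrella force at the current reference point).
#'
#' @param state List with `z`, `v`, `theta`, `vtheta`.
#' @param landscape A `toy_landscape`.
#' @param bias_force Constant bias force on z over this step, kJ/mol/nm.
#' @param params An [integrator_params()].
#' @param seed Seed for this step's noise.
#' @param lambda_index 1-based lambda state.
#' @return The updated state list.
#' @export
langevin_step <- function(state, landscape, bias_force = 0,
                          params = integrator_params(), seed = 1,
                          lambda_index = 1) {
  if (!is.finite(bias_force)) {
    abort_numerical("non-finite bias force in langevin_step")
  }
  m <- langevin_run_cpp(unclass(landscape), as.integer(lambda_index) - 1L,
                        1L, params$dt, params$friction, params$mass,
                        params$kT, as.double(seed),
                        state$z, state$v, state$theta, state$vtheta,
                        1L, 0, 0, bias_force)
  list(z = m[1, "z"], v = m[1, "v"], theta = m[1, "theta"],
       vtheta = m[1, "vtheta"])
}
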