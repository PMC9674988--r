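#' Built-in synthetic model systems
#'
#' Ready-made toy landscapes standing in for the all-atom membrane barrier
#' system. They are generated analytically (no stored data) and are the
#' study systems for the package's validation suite: their exact PMFs and
#' solvation free energies are available by quadrature
#' ([reference_pmf()], [reference_solvation()]).
#'
#' * `default_membrane_landscape()`: the full-size profile over a 5.21 nm
#'   half-period - two Gaussian barriers (25 and 15 kJ/mol) and a 10 kJ/mol
#'   trap well per half-period on a -10 kJ/mol solvent level, echoing the
#'   qualitative shape of a stratum-corneum lamella PMF.
#' * `desk_membrane_landscape()`: a 2.6 nm desk-scale variant (barriers 10
#'   and 6 kJ/mol, well 5 kJ/mol, solvent level -4 kJ/mol) sized so adaptive
#'   sampling converges in minutes on one CPU.
#' * `gel_trap_landscape()`: the desk membrane plus a slow orientational
#'   degree of freedom: a 6 kJ/mol favourable-orientation depth behind a
#'   25 kJ/mol orientational barrier localized inside the membrane. At full
#'   coupling the orientational relaxation time vastly exceeds the spatial
#'   diffusion time (gel-phase trapping); at full decoupling the barrier
#'   vanishes, which is what a 2D spatial x alchemical reaction coordinate
#'   exploits.
#' * `solvent_box_landscape()`: featureless solvent with an optional
#'   harmonic orientational coupling, for solvation free-energy runs with a
#'   closed-form (Gaussian-integral) reference.
#' * `two_state_landscape()`: a 2-state alchemical toy (solvent coupling
#'   only) whose exact free-energy difference is known by quadrature.
#'
#' @param n_lambda Number of lambda states (default 21; use 1 for
#'   spatial-only sampling).
#' @param solvent_level Coupled solvent plateau, kJ/mol.
#' @param theta_k Harmonic orientational spring constant, kJ/mol/rad^2
#'   (`solvent_box_landscape`; 0 disables the orientational term).
#' @name model_systems
NULL

#' @rdname model_systems
#' @export
default_membrane_landscape <- function(n_lambda = 21) {
  build_landscape(list(
    L = 5.21, solvent_level = -10, solvent_z = 4.9,
    barriers = data.frame(center = c(1.3, 2.9), height = c(25, 15),
                          width = c(0.30, 0.30)),
    wells = data.frame(center = 2.1, depth = 10, width = 0.25),
    schedule = lambda_schedule(n_lambda)
  ))
}

#' @rdname model_systems
#' @export
desk_membrane_landscape <- function(n_lambda = 11) {
  build_landscape(list(
    L = 2.6, solvent_level = -4, solvent_z = 2.35,
    barriers = data.frame(center = c(0.7, 1.5), height = c(10, 6),
                          width = c(0.18, 0.18)),
    wells = data.frame(center = 1.1, depth = 5, width = 0.18),
    schedule = lambda_schedule(n_lambda)
  ))
}

#' @rdname model_systems
#' @export
gel_trap_landscape <- function(n_lambda = 11) {
  build_landscape(list(
    L = 2.6, solvent_level = -4, solvent_z = 2.35,
    barriers = data.frame(center = c(0.7, 1.5), height = c(10, 6),
                          width = c(0.18, 0.18)),
    wells = data.frame(center = 1.1, depth = 5, width = 0.18),
    theta = "trap",
    trap = list(center = 1.1, width = 0.35, depth = 6, barrier = 25),
    schedule = lambda_schedule(n_lambda)
  ))
}

#' @rdname model_systems
#' @export
solvent_box_landscape <- function(n_lambda = 21, solvent_level = -4,
                                  theta_k = 20) {
  spec <- list(L = 1, solvent_level = solvent_level, solvent_z = 0.5,
               schedule = lambda_schedule(n_lambda))
  if (theta_k > 0) {
    spec$theta <- "harmonic"
    spec$theta_k <- theta_k
  }
  build_landscape(spec)
}

#' @rdname model_systems
#' @export
two_state_landscape <- function(solvent_level = -3) {
  solvent_box_landscape(n_lambda = 2, solvent_level = solvent_level,
                        theta_k = 15)
}

#' Desk-scale AWH configuration for the built-in toys
#'
#' The production configuration with the scale-dependent entries re-estimated
#' for the desk-scale model systems: the input diffusion constants are set to
#' the toys' actual mobilities (reference-point hopping at the toy umbrella
#' stiffness is orders of magnitude faster than permeant diffusion in a
#' lipid lamella), and the umbrella force constant 2,500 kJ/mol/nm^2 matches
#' the 0.02 nm grid resolution the desk toys use (the umbrella width sets
#' the reaction-coordinate resolution, so a softer umbrella than production
#' pairs with the coarser desk grid). Everything else keeps the production
#' defaults.
#'
#' @param n_walkers Number of communicating walkers (default 4).
#' @param ... Overrides passed to [awh_config()].
#' @return An [awh_config()].
#' @export
desk_awh_config <- function(n_walkers = 4, ...) {
  args <- list(...)
  defaults <- list(n_walkers = n_walkers,
                   force_constant = 2500,
                   input_diffusion_spatial = 2e-3,
                   input_diffusion_lambda = 5e-2)
  do.call(awh_config, utils::modifyList(defaults, args))
}
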