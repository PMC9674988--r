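#' Alchemical coupling schedule
#'
#' A set of equidistant lambda states interpolating between the fully
#' interacting permeant (state 1, lambda value 0) and one fully decoupled from
#' its environment (last state, lambda value 1, vacuum-like). A single scalar
#' scales all permeant-environment interactions simultaneously
#' (`coupling_mode = "simultaneous"`); sequential Coulomb-then-dispersion
#' schedules are deliberately not provided because simultaneous switching
#' avoids orientational locking in gel-phase environments.
#'
#' @param n_states Number of lambda states (default 21).
#' @return A `lambda_schedule` object: list with `n_states`, `values`
#'   (equidistant in `[0, 1]`) and `coupling_mode`.
#' @examples
#' lambda_schedule(21)$values[c(1, 21)]  # 0 and 1
#' @export
lambda_schedule <- function(n_states = 21) {
  if (!is.numeric(n_states) || length(n_states) != 1L || n_states < 1 ||
      n_states != round(n_states)) {
    abort_validation("`n_states` must be a positive integer")
  }
  n_states <- as.integer(n_states)
  values <- if (n_states == 1L) 0 else seq(0, 1, length.out = n_states)
  structure(
    list(n_states = n_states, values = values,
         coupling_mode = "simultaneous"),
    class = "lambda_schedule"
  )
}

#' Soft-core coupling parameters
#'
#' Parameters of the soft-core transformation applied to the repulsive part of
#' the permeant-environment interaction at intermediate lambda. The repulsive
#' energy `E` is mapped to an effective inverse-12 pair distance through
#' `E = epsilon * (sigma / r)^12` and the Beutler form
#' `V = (1 - lambda) epsilon sigma^12 / (alpha sigma^6 lambda + r^6)^2`
#' is evaluated, which caps the energy at
#' `(1 - lambda) epsilon / (alpha lambda)^2` however large the fully coupled
#' interaction is. With the inverse-12 energy-to-distance map, `sigma` cancels
#' algebraically and acts purely as the documented length scale of the mapping.
#'
#' @param alpha Soft-core alpha (dimensionless, default 0.5).
#' @param sigma Soft-core sigma in nm (default 0.3).
#' @param epsilon Energy scale of the effective pair term in kJ/mol
#'   (default 1).
#' @return A `softcore_params` object.
#' @export
softcore_params <- function(alpha = 0.5, sigma = 0.3, epsilon = 1) {
  if (!is.finite(alpha) || alpha < 0) {
    abort_validation("soft-core `alpha` must be finite and >= 0")
  }
  if (!is.finite(sigma) || sigma <= 0) {
    abort_validation("soft-core `sigma` must be finite and > 0")
  }
  if (!is.finite(epsilon) || epsilon <= 0) {
    abort_validation("soft-core `epsilon` must be finite and > 0")
  }
  structure(list(alpha = alpha, sigma = sigma, epsilon = epsilon),
            class = "softcore_params")
}

#' Soft-core coupled pair energy
#'
#' Direct evaluation of the soft-core form used by the landscape potential:
#' the fully coupled repulsive energy `E` is attenuated at intermediate
#' lambda and capped, and vanishes at full decoupling.
#'
#' @param E Fully coupled repulsive energy, kJ/mol (vectorised).
#' @param lambda Coupling value(s) in `[0, 1]`.
#' @param sc A [softcore_params()] object.
#' @return Soft-core energy in kJ/mol.
#' @export
softcore_energy <- function(E, lambda, sc = softcore_params()) {
  stopifnot(all(E >= 0), all(lambda >= 0 & lambda <= 1))
  n <- max(length(E), length(lambda))
  E <- rep_len(E, n)
  lambda <- rep_len(lambda, n)
  out <- (1 - lambda) * sc$epsilon /
    (sc$alpha * lambda + sqrt(sc$epsilon / pmax(E, 1e-12)))^2
  small <- E < 1e-12
  out[small] <- (1 - lambda[small]) * E[small]
  out[lambda >= 1] <- 0
  out
}

#' Build a synthetic lambda-coupled membrane landscape
#'
#' Constructs a toy free-energy landscape standing in for an all-atom
#' membrane system: a one-dimensional membrane profile `G_mem(z)` over
#' `z in [0, L]` composed of Gaussian barriers and wells on top of a constant
#' solvent level, optionally augmented with a slow orientational degree of
#' freedom `theta` (a "gel-phase" trap whose barrier vanishes on decoupling),
#' and an alchemical coupling axis along which a single scalar lambda scales
#' all permeant-environment terms. At the fully decoupled state the total
#' potential is identically zero, independent of `z` and `theta`.
#'
#' @param spec A list with elements:
#'   * `L`: domain length in nm (default 5.21, the half-system extent of the
#'     membrane stack the defaults emulate);
#'   * `solvent_level`: plateau free energy of the coupled permeant in the
#'     solvent region, kJ/mol (relative to the decoupled/vacuum state);
#'   * `barriers`: data frame with `center`, `height` (> 0), `width` (nm);
#'   * `wells`: data frame with `center`, `depth` (> 0), `width` (nm);
#'   * `trap`: optional list `(center, width, depth, barrier)` for the
#'     orientational trap: the permeant gains `depth` kJ/mol in its
#'     favourable orientation, separated by an orientational `barrier`
#'     localized around `center` with Gaussian envelope `width`;
#'   * `theta`: `"none"`, `"trap"` or `"harmonic"`; `theta_k` gives the
#'     harmonic spring constant (kJ/mol/rad^2) for the harmonic mode;
#'   * `boundary`: `"reflective"` (default) or `"periodic"`;
#'   * `solvent_z`: a z position on the solvent plateau (default `0.95 * L`);
#'   * `schedule`: a [lambda_schedule()]; `softcore`: a [softcore_params()].
#' @return A `toy_landscape` object.
#' @examples
#' land <- build_landscape(list(
#'   L = 2, solvent_level = -4,
#'   barriers = data.frame(center = 0.7, height = 10, width = 0.2)
#' ))
#' @export
build_landscape <- function(spec = list()) {
  defaults <- list(
    L = 5.21, solvent_level = 0,
    barriers = NULL, wells = NULL, trap = NULL,
    theta = NULL, theta_k = 0,
    boundary = "reflective", solvent_z = NULL,
    schedule = lambda_schedule(), softcore = softcore_params()
  )
  spec <- utils::modifyList(defaults, spec)
  if (!is.finite(spec$L) || spec$L <= 0) {
    abort_validation("landscape `L` must be finite and > 0")
  }
  if (!is.finite(spec$solvent_level)) {
    abort_validation("`solvent_level` must be finite")
  }
  if (!spec$boundary %in% c("reflective", "periodic")) {
    abort_validation('`boundary` must be "reflective" or "periodic"')
  }
  if (is.null(spec$solvent_z)) spec$solvent_z <- 0.95 * spec$L

  gh <- numeric(0); gc_ <- numeric(0); gw <- numeric(0)
  add_feat <- function(df, sign, what) {
    if (is.null(df) || nrow(df) == 0) return(invisible())
    amp <- if (sign > 0) df$height else -df$depth
    if (any(!is.finite(amp)) || any(!is.finite(df$center)) ||
        any(!is.finite(df$width)) || any(df$width <= 0)) {
      abort_validation(sprintf("non-finite or invalid %s parameters", what))
    }
    if (any(abs(amp) > 200)) {
      abort_validation(sprintf("%s heights must be within +/-200 kJ/mol", what))
    }
    if (sign > 0 && any(df$height <= 0)) {
      abort_validation("barrier heights must be > 0")
    }
    if (sign < 0 && any(df$depth <= 0)) {
      abort_validation("well depths must be > 0")
    }
    gh <<- c(gh, amp); gc_ <<- c(gc_, df$center); gw <<- c(gw, df$width)
    invisible()
  }
  add_feat(spec$barriers, +1, "barrier")
  add_feat(spec$wells, -1, "well")

  # heavily overlapping same-sign Gaussians are ill-conditioned but legal
  if (length(gh) > 1) {
    for (i in seq_len(length(gh) - 1)) {
      for (j in seq(i + 1, length(gh))) {
        if (sign(gh[i]) == sign(gh[j]) &&
            abs(gc_[i] - gc_[j]) < 0.2 * (gw[i] + gw[j])) {
          warn("overlapping Gaussian features are ill-conditioned; proceeding")
        }
      }
    }
  }

  theta_mode <- 0L
  trap <- list(center = 0, width = 1, depth = 0, barrier = 0)
  theta_k <- 0
  if (!is.null(spec$trap) || identical(spec$theta, "trap")) {
    if (is.null(spec$trap)) {
      abort_validation("theta = \"trap\" requires a `trap` list")
    }
    trap <- utils::modifyList(trap, spec$trap)
    if (any(!is.finite(unlist(trap))) || trap$width <= 0) {
      abort_validation("non-finite or invalid trap parameters")
    }
    theta_mode <- 1L
  } else if (identical(spec$theta, "harmonic")) {
    theta_k <- spec$theta_k
    if (!is.finite(theta_k) || theta_k <= 0) {
      abort_validation("harmonic theta mode requires `theta_k` > 0")
    }
    theta_mode <- 2L
  }

  structure(
    list(
      L = spec$L,
      boundary = spec$boundary,
      solvent_level = spec$solvent_level,
      gauss_height = gh, gauss_center = gc_, gauss_width = gw,
      theta_mode = theta_mode,
      trap_depth = trap$depth, trap_barrier = trap$barrier,
      trap_center = trap$center, trap_width = trap$width,
      theta_k = theta_k,
      softcore = unclass(spec$softcore),
      schedule = spec$schedule,
      lambda_values = spec$schedule$values,
      solvent_z = spec$solvent_z
    ),
    class = "toy_landscape"
  )
}

#' @export
print.toy_landscape <- function(x, ...) {
  cat(sprintf(
    "<toy_landscape> L = %g nm (%s), solvent level %g kJ/mol, %d Gaussian feature(s),\n  theta mode %s, %d lambda state(s)\n",
    x$L, x$boundary, x$solvent_level, length(x$gauss_height),
    c("none", "trap", "harmonic")[x$theta_mode + 1L],
    x$schedule$n_states))
  invisible(x)
}

#' Membrane profile at full coupling, without the orientational term
#'
#' `G_mem(z) = solvent_level + sum of Gaussian features`; this is the analytic
#' potential the landscape was configured with, before integrating out theta.
#'
#' @param landscape A `toy_landscape`.
#' @param z Positions (nm).
#' @return Energies in kJ/mol.
#' @export
membrane_profile <- function(landscape, z) {
  out <- rep(landscape$solvent_level, length(z))
  for (i in seq_along(landscape$gauss_height)) {
    out <- out + landscape$gauss_height[i] *
      exp(-0.5 * ((z - landscape$gauss_center[i]) / landscape$gauss_width[i])^2)
  }
  out
}

#' Total coupled potential of the toy landscape
#'
#' Evaluates `U(z, theta, lambda)` with soft-core attenuation of the repulsive
#' part and linear attenuation of the attractive and orientational parts. At
#' the last lambda state the result is identically 0 (decoupled).
#'
#' @param landscape A `toy_landscape`.
#' @param z Positions (nm); values outside `[0, L]` are mapped by the
#'   landscape's boundary convention (reflective or periodic), never
#'   extrapolated.
#' @param theta Orientation angle(s), radians (recycled).
#' @param lambda_index 1-based index into the lambda schedule.
#' @return Energies in kJ/mol.
#' @export
potential <- function(landscape, z, theta = 0, lambda_index = 1) {
  stopifnot(inherits(landscape, "toy_landscape"))
  n_lam <- landscape$schedule$n_states
  if (lambda_index < 1 || lambda_index > n_lam) {
    abort_validation(sprintf("lambda_index must be in 1..%d", n_lam))
  }
  z <- map_into_domain(z, landscape)
  theta <- rep_len(theta, length(z))
  potential_cpp(unclass(landscape), z, theta, as.integer(lambda_index) - 1L)
}

# boundary convention for out-of-domain z: reflect or wrap, never extrapolate
map_into_domain <- function(z, landscape) {
  L <- landscape$L
  if (landscape$boundary == "periodic") {
    z <- z %% L
  } else {
    z <- abs(z)
    z <- ifelse((z %/% L) %% 2 == 0, z %% L, L - (z %% L))
  }
  z
}

#' Analytic reference PMF by quadrature
#'
#' The potential of mean force along z at a fixed lambda state, obtained by
#' numerical quadrature over the orientational degree of freedom:
#' `F(z) = -kT log[(1/2pi) int exp(-beta U(z, theta, lambda)) dtheta]`.
#' Used as the independent oracle the adaptive sampler is validated against.
#' Without an orientational degree of freedom the PMF equals `G_mem` exactly.
#'
#' @param landscape A `toy_landscape`.
#' @param lambda_index 1-based lambda state index (default 1, fully coupled).
#' @param z Grid of positions (nm), or an [awh_grid()] whose z centers are
#'   used.
#' @param thermo A [thermo_params()].
#' @param anchor `"solvent"` (plateau at `solvent_z` set to 0, the default),
#'   `"vacuum"` (referenced to the decoupled state, i.e. unshifted) or
#'   `"none"` (alias for vacuum).
#' @param n_theta Number of quadrature nodes over `[-pi, pi)` (default 512).
#' @return A [pmf_profile()] with the matching reference tag.
#' @export
reference_pmf <- function(landscape, lambda_index = 1, z,
                          thermo = thermo_params(),
                          anchor = c("solvent", "vacuum", "none"),
                          n_theta = 512) {
  stopifnot(inherits(landscape, "toy_landscape"))
  anchor <- match.arg(anchor)
  if (inherits(z, "awh_grid")) z <- z$z
  if (any(z < -1e-9) || any(z > landscape$L + 1e-9)) {
    abort_validation("reference_pmf grid must lie within [0, L]")
  }
  f <- free_energy_quadrature(landscape, z, lambda_index, thermo, n_theta)
  if (!all(is.finite(f))) {
    abort_numerical("quadrature produced non-finite free energies")
  }
  se <- NULL
  if (anchor == "solvent") {
    f0 <- free_energy_quadrature(landscape, landscape$solvent_z, lambda_index,
                                 thermo, n_theta)
    f <- f - f0
    tag <- "solvent"
  } else {
    tag <- "vacuum"  # decoupled state is exactly 0 by construction
  }
  pmf_profile(z = z, dG = f, se = se, reference = tag)
}

# -kT log of the theta-average Boltzmann weight, vectorised over z
free_energy_quadrature <- function(landscape, z, lambda_index, thermo,
                                   n_theta) {
  if (landscape$theta_mode == 0L) {
    return(potential(landscape, z, 0, lambda_index))
  }
  th <- seq(-pi, pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  beta <- thermo$beta
  vapply(z, function(zi) {
    u <- potential(landscape, rep(zi, n_theta), th, lambda_index)
    m <- min(u)
    -thermo$kT * (log(mean(exp(-beta * (u - m)))) - beta * m)
  }, numeric(1))
}

#' Reference solvation free energy by quadrature
#'
#' Free energy of coupling the permeant into the solvent region of the
#' landscape: `dG_solv = F(z_solvent, lambda = 0) - F(z_solvent, decoupled)`,
#' the toy analogue of a hydration free energy. Negative values mean
#' favourable solvation. This quantity calibrates vacuum-referenced PMFs to
#' the solvent reference state.
#'
#' @inheritParams reference_pmf
#' @return Scalar free energy in kJ/mol.
#' @export
reference_solvation <- function(landscape, thermo = thermo_params(),
                                n_theta = 2048) {
  stopifnot(inherits(landscape, "toy_landscape"))
  # decoupled free energy is 0 by construction
  free_energy_quadrature(landscape, landscape$solvent_z, 1L, thermo, n_theta)
}
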