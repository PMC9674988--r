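#' Potential of mean force profile
#'
#' A tidy container for a free-energy profile along the membrane normal:
#' `dG(z)` in kJ/mol on a strictly increasing z grid (nm), with optional
#' per-bin standard errors and a reference-state tag: `"vacuum"` when the
#' profile is referenced to the fully decoupled state, `"solvent"` after
#' calibration relative to the solvation free energy (the form entering the
#' layer-scaled resistance integral).
#'
#' @param z Grid positions, nm (strictly increasing).
#' @param dG Free energies, kJ/mol.
#' @param se Optional standard errors, kJ/mol.
#' @param reference `"vacuum"` or `"solvent"`.
#' @return A tibble of class `pmf_profile` with attribute `reference_tag`.
#' @export
pmf_profile <- function(z, dG, se = NULL, reference = c("solvent", "vacuum")) {
  reference <- match.arg(reference)
  if (length(z) != length(dG)) abort_validation("`z` and `dG` lengths differ")
  if (any(!is.finite(z))) abort_validation("non-finite grid positions")
  if (any(diff(z) <= 0)) abort_validation("grid must be strictly increasing")
  if (is.null(se)) se <- rep(NA_real_, length(z))
  out <- tibble(z = as.numeric(z), dG = as.numeric(dG), se = as.numeric(se))
  class(out) <- c("pmf_profile", class(out))
  attr(out, "reference_tag") <- reference
  out
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("# PMF profile (%s-referenced), %d bins, z in [%g, %g] nm\n",
              attr(x, "reference_tag"), nrow(x), min(x$z), max(x$z)))
  NextMethod()
}

#' Local diffusion profile
#'
#' `D(z)` in nm^2/ps on a z grid, with optional cross-walker standard errors
#' and filter metadata. Missing bins (never sampled) carry `NA` and are never
#' zero-filled.
#'
#' @param z Grid positions, nm (strictly increasing).
#' @param D Diffusion coefficients, nm^2/ps (positive where defined).
#' @param se Optional standard errors.
#' @return A tibble of class `diffusion_profile`.
#' @export
diffusion_profile <- function(z, D, se = NULL) {
  if (length(z) != length(D)) abort_validation("`z` and `D` lengths differ")
  if (any(diff(z) <= 0)) abort_validation("grid must be strictly increasing")
  if (any(D[!is.na(D)] <= 0)) {
    abort_validation("diffusion coefficients must be positive where defined")
  }
  if (is.null(se)) se <- rep(NA_real_, length(z))
  if (any(se[!is.na(se)] < 0)) abort_validation("standard errors must be >= 0")
  out <- tibble(z = as.numeric(z), D = as.numeric(D), se = as.numeric(se))
  class(out) <- c("diffusion_profile", class(out))
  out
}

#' Calibrate a vacuum-referenced PMF to the solvent reference
#'
#' Subtracts the solvation free energy so the profile becomes the free energy
#' relative to the reference solvent (`dG_rel.water` in the layer-scaled
#' resistance integral): the calibrated profile is approximately 0 wherever
#' the environment equals the reference solvent.
#'
#' @param pmf A vacuum-referenced [pmf_profile()].
#' @param dG_solv Solvation free energy, kJ/mol (insertion convention, e.g.
#'   from [reference_solvation()], [solvation_free_energy()] or
#'   [run_solvation()]).
#' @return A solvent-referenced [pmf_profile()].
#' @export
calibrate_relative_to_solvent <- function(pmf, dG_solv) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (identical(attr(pmf, "reference_tag"), "solvent")) {
    abort_validation("profile is already solvent-calibrated")
  }
  if (!is.finite(dG_solv)) abort_validation("`dG_solv` must be finite")
  pmf$dG <- pmf$dG - dG_solv
  attr(pmf, "reference_tag") <- "solvent"
  pmf
}

#' Shift a PMF so it is never below zero
#'
#' Chooses the additive constant of the PMF so its minimum is exactly 0, the
#' convention used before evaluating the resistance integral.
#'
#' @param pmf A [pmf_profile()].
#' @return The shifted profile.
#' @export
offset_nonnegative <- function(pmf) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (any(!is.finite(pmf$dG))) abort_validation("PMF contains non-finite values")
  pmf$dG <- pmf$dG - min(pmf$dG)
  pmf
}

#' Replace edge spikes by their inner neighbours
#'
#' Symmetrized sampling across the boundaries commonly leaves artificial
#' spikes at the outermost PMF points; the first and last `n_edge` values are
#' replaced by the value of their innermost retained neighbour (grid
#' unchanged).
#'
#' @param pmf A [pmf_profile()].
#' @param n_edge Number of points to replace at each end (default 2).
#' @return The trimmed profile.
#' @export
trim_edges <- function(pmf, n_edge = 2) {
  stopifnot(inherits(pmf, "pmf_profile"))
  n_edge <- as.integer(n_edge)
  if (n_edge < 0) abort_validation("`n_edge` must be >= 0")
  if (n_edge == 0) return(pmf)
  n <- nrow(pmf)
  if (n <= 2L * n_edge + 1L) {
    abort_validation("profile too short for the requested edge trim")
  }
  pmf$dG[seq_len(n_edge)] <- pmf$dG[n_edge + 1L]
  pmf$dG[seq(n - n_edge + 1L, n)] <- pmf$dG[n - n_edge]
  pmf
}

#' Permeation resistance integral
#'
#' Evaluates the inhomogeneous solubility-diffusion resistance
#' `R = integral exp(beta dG(z)) / D(z) dz` over the profile grid by
#' composite trapezoid (Simpson available by flag). The PMF must be
#' solvent-calibrated and non-negative; the diffusion profile is linearly
#' interpolated onto the PMF grid when the grids differ by more than 1e-9 nm
#' (with a warning). Missing diffusion values inside the integration range
#' are an error.
#'
#' @param pmf A solvent-referenced, non-negativity-offset [pmf_profile()].
#' @param dp A [diffusion_profile()].
#' @param thermo A [thermo_params()].
#' @param method `"trapezoid"` (default) or `"simpson"`.
#' @return Resistance in native units, ps/nm (convert with
#'   [total_permeability()]).
#' @export
resistance <- function(pmf, dp, thermo = thermo_params(),
                       method = c("trapezoid", "simpson")) {
  stopifnot(inherits(pmf, "pmf_profile"), inherits(dp, "diffusion_profile"))
  method <- match.arg(method)
  if (!identical(attr(pmf, "reference_tag"), "solvent")) {
    abort_validation("PMF must be solvent-calibrated before the resistance integral")
  }
  if (min(pmf$dG) < -1e-9) {
    abort_validation("apply offset_nonnegative() before the resistance integral")
  }
  D <- align_diffusion(pmf, dp)
  if (any(is.na(D))) {
    abort_validation("missing diffusion values inside the integration range")
  }
  if (any(D <= 0)) abort_validation("diffusion must be positive")
  integrand <- exp(thermo$beta * pmf$dG) / D
  if (!all(is.finite(integrand))) {
    abort_numerical("non-finite resistance integrand (PMF too large?)")
  }
  z <- pmf$z
  if (method == "trapezoid") {
    sum(diff(z) * (head(integrand, -1) + tail(integrand, -1)) / 2)
  } else {
    simpson_composite(z, integrand)
  }
}

align_diffusion <- function(pmf, dp) {
  if (nrow(dp) == nrow(pmf) && max(abs(dp$z - pmf$z)) <= 1e-9) {
    return(dp$D)
  }
  warn("diffusion grid differs from PMF grid; interpolating linearly")
  if (min(pmf$z) < min(dp$z) - 1e-9 || max(pmf$z) > max(dp$z) + 1e-9) {
    abort_validation("diffusion profile does not span the PMF grid")
  }
  approx(dp$z, dp$D, xout = pmf$z)$y
}

# composite Simpson on a uniform grid; falls back to trapezoid on the last
# interval when the point count is even
simpson_composite <- function(z, y) {
  n <- length(z)
  dz <- diff(z)
  if (max(dz) - min(dz) > 1e-9) {
    abort_validation("Simpson integration requires a uniform grid")
  }
  h <- dz[1]
  total <- 0
  m <- if (n %% 2 == 1) n else n - 1
  if (m >= 3) {
    i <- seq(1, m - 2, by = 2)
    total <- sum(h / 3 * (y[i] + 4 * y[i + 1] + y[i + 2]))
  }
  if (m < n) total <- total + h * (y[n - 1] + y[n]) / 2
  total
}

#' Bilayer layer-count model
#'
#' The number of stacked bilayers the permeant crosses in a full barrier
#' structure: `n_regions` intercellular lipid regions times
#' `bilayers_per_region` bilayers each, with independent standard errors
#' combined by first-order (delta-method) propagation. The defaults
#' (12 +/- 0.4 regions of 2.5 +/- 0.5 bilayers) give 30 +/- 6 total bilayers.
#'
#' @param n_regions,n_regions_se Mean and SE of the number of intercellular
#'   lipid regions.
#' @param bilayers_per_region,bilayers_se Mean and SE of the bilayers per
#'   region.
#' @return A `layer_model` object.
#' @export
layer_model <- function(n_regions = 12, n_regions_se = 0.4,
                        bilayers_per_region = 2.5, bilayers_se = 0.5) {
  if (n_regions <= 0 || bilayers_per_region <= 0) {
    abort_validation("layer-model means must be > 0")
  }
  if (n_regions_se < 0 || bilayers_se < 0) {
    abort_validation("layer-model SEs must be >= 0")
  }
  structure(
    list(n_regions = n_regions, n_regions_se = n_regions_se,
         bilayers_per_region = bilayers_per_region,
         bilayers_se = bilayers_se),
    class = "layer_model"
  )
}

#' Total bilayer count with propagated uncertainty
#'
#' Product of the layer-model means, with the SE of a product of independent
#' quantities by the delta method:
#' `se = sqrt((b * se_a)^2 + (a * se_b)^2)`. Rounding happens only at
#' reporting, never here.
#'
#' @param lm A [layer_model()].
#' @return List with `mean` and `se`.
#' @export
layer_count <- function(lm = layer_model()) {
  stopifnot(inherits(lm, "layer_model"))
  mean <- lm$n_regions * lm$bilayers_per_region
  se <- sqrt((lm$bilayers_per_region * lm$n_regions_se)^2 +
             (lm$n_regions * lm$bilayers_se)^2)
  list(mean = mean, se = se)
}

#' Permeability coefficient through the stacked barrier
#'
#' Scales the single-period resistance by the total bilayer count,
#' `R_total = n_total * R_single`, converts to experimental units and reports
#' `K_P = 1 / R_total` in cm/h together with `log10 K_P` and its propagated
#' standard error. By default only the layer-count uncertainty is propagated
#' (`se(log10 K_P) = se_n / (n ln 10)`); an optional resistance SE is added
#' in quadrature on the relative scale.
#'
#' @param R_single Single-period resistance. In native units (ps/nm, as
#'   returned by [resistance()]) when `units = "nm_ps"`; already in h/cm when
#'   `units = "cm_h"`.
#' @param lm A [layer_model()] (pass `layer_model(1, 0, 1, 0)` for a single
#'   layer).
#' @param thermo A [thermo_params()] (recorded with the result).
#' @param se_R Optional standard error of `R_single`, same units.
#' @param units Units of `R_single`.
#' @return A `permeability_result`: list with `R` (h/cm), `K_P` (cm/h),
#'   `log10_KP`, `se_log10_KP`, `n_layers`, `layer_model`, `beta`.
#' @export
total_permeability <- function(R_single, lm = layer_model(),
                               thermo = thermo_params(), se_R = NULL,
                               units = c("nm_ps", "cm_h")) {
  units <- match.arg(units)
  if (!is.finite(R_single) || R_single <= 0) {
    abort_validation("`R_single` must be positive and finite")
  }
  lc <- layer_count(lm)
  R_single_hcm <- if (units == "nm_ps") R_single / NM_PS_TO_CM_H else R_single
  se_R_hcm <- if (is.null(se_R)) NULL else {
    if (units == "nm_ps") se_R / NM_PS_TO_CM_H else se_R
  }
  R_total <- lc$mean * R_single_hcm
  K_P <- 1 / R_total
  rel_var <- (lc$se / lc$mean)^2
  if (!is.null(se_R_hcm)) rel_var <- rel_var + (se_R_hcm / R_single_hcm)^2
  structure(
    list(R = R_total, K_P = K_P, log10_KP = log10(K_P),
         se_log10_KP = sqrt(rel_var) / log(10),
         n_layers = lc, layer_model = lm, beta = thermo$beta,
         R_single = R_single_hcm),
    class = "permeability_result"
  )
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf(
    "<permeability_result> %.3g (+/- %.2g) bilayers\n  R = %.4g h/cm, K_P = %.4g cm/h, log10 K_P = %.3f +/- %.3f\n",
    x$n_layers$mean, x$n_layers$se, x$R, x$K_P, x$log10_KP, x$se_log10_KP))
  invisible(x)
}

#' Combine independent simulation sets
#'
#' Per-bin mean and standard error over the PMFs from independent sets of
#' simulations; the combined profile is what enters the permeability
#' pipeline. A single set yields no reliable error estimate (the bias is
#' shared between communicating walkers), so `se` stays `NA` with a warning.
#'
#' @param profiles List of [pmf_profile()]s on identical grids with the same
#'   reference tag.
#' @return A combined [pmf_profile()] with per-bin `se`.
#' @export
combine_sets <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "pmf_profile")))
  z0 <- profiles[[1]]$z
  tags <- vapply(profiles, function(p) attr(p, "reference_tag"), character(1))
  if (length(unique(tags)) != 1) {
    abort_validation("profiles have inconsistent reference tags")
  }
  for (p in profiles[-1]) {
    if (nrow(p) != length(z0) || max(abs(p$z - z0)) > 1e-9) {
      abort_validation("profiles are not on a common grid")
    }
  }
  m <- vapply(profiles, function(p) p$dG, numeric(length(z0)))
  m <- matrix(m, nrow = length(z0))
  if (length(profiles) == 1) {
    warn("a single simulation set gives no reliable error estimate")
    return(pmf_profile(z0, m[, 1], reference = tags[1]))
  }
  pmf_profile(z0, rowMeans(m),
              se = apply(m, 1, sd) / sqrt(ncol(m)),
              reference = tags[1])
}

#' Full solubility-diffusion permeability pipeline
#'
#' Convenience wrapper chaining the post-processing steps on one or more
#' PMF sets: combine sets, optionally calibrate to the solvent reference,
#' remove edge spikes, offset to non-negative, integrate the resistance and
#' scale by the layer count.
#'
#' @param pmf A [pmf_profile()] or list of them (independent sets).
#' @param dp A [diffusion_profile()].
#' @param lm A [layer_model()].
#' @param thermo A [thermo_params()].
#' @param dG_solv Solvation free energy for calibration when the (combined)
#'   profile is vacuum-referenced; ignored for solvent-referenced input.
#' @param n_edge Edge points replaced by [trim_edges()] (default 2; 0 skips).
#' @param uncertainty `"layers"` (delta-method on the layer count, default)
#'   or `"mc"` (additionally resamples the PMF within its per-bin SE,
#'   `n_mc` draws, and adds the spread of `log10 K_P` in quadrature).
#' @param n_mc Monte Carlo draws for `uncertainty = "mc"`.
#' @param seed Seed for the Monte Carlo propagation.
#' @return A `permeability_result` with the combined profile attached as
#'   attribute `"pmf"`.
#' @export
permeability_pipeline <- function(pmf, dp, lm = layer_model(),
                                  thermo = thermo_params(), dG_solv = NULL,
                                  n_edge = 2,
                                  uncertainty = c("layers", "mc"),
                                  n_mc = 200, seed = 1) {
  uncertainty <- match.arg(uncertainty)
  if (inherits(pmf, "pmf_profile")) pmf <- list(pmf)
  combined <- if (length(pmf) > 1) combine_sets(pmf) else pmf[[1]]
  if (identical(attr(combined, "reference_tag"), "vacuum")) {
    if (is.null(dG_solv)) {
      abort_validation("vacuum-referenced PMF needs `dG_solv` for calibration")
    }
    combined <- calibrate_relative_to_solvent(combined, dG_solv)
  }
  prep <- function(p) offset_nonnegative(trim_edges(p, n_edge))
  ready <- prep(combined)
  R1 <- resistance(ready, dp, thermo)
  res <- total_permeability(R1, lm, thermo)
  if (uncertainty == "mc" && !all(is.na(combined$se))) {
    rng <- init_unit_normals(seed, n_mc * nrow(combined))
    draws <- vapply(seq_len(n_mc), function(b) {
      eps <- rng[((b - 1) * nrow(combined) + 1):(b * nrow(combined))]
      se <- ifelse(is.na(combined$se), 0, combined$se)
      p <- combined
      p$dG <- combined$dG + eps * se
      log10(1 / (res$n_layers$mean *
                   resistance(prep(p), dp, thermo) / NM_PS_TO_CM_H))
    }, numeric(1))
    res$se_log10_KP <- sqrt(res$se_log10_KP^2 + var(draws))
  }
  attr(res, "pmf") <- combined
  res
}

# seeded standard normals that leave the caller's RNG state untouched
init_unit_normals <- function(seed, n) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n)
}
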