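#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an AWH sampling result
#'
#' One row per reaction-coordinate grid point with the free-energy estimate,
#' target probability and accumulated sample weight.
#'
#' @param x An `awh_result`.
#' @param ... Unused.
#' @return A tibble with columns `z`, `lambda_index`, `lambda`, `f`,
#'   `target`, `visits`.
#' @export
tidy.awh_result <- function(x, ...) {
  grid <- x$grid
  lam <- x$landscape$lambda_values
  tibble(
    z = rep(grid$z, times = grid$n_lambda),
    lambda_index = rep(seq_len(grid$n_lambda), each = grid$n_z),
    lambda = rep(lam, each = grid$n_z),
    f = as.numeric(x$bias$f),
    target = as.numeric(x$bias$target),
    visits = as.numeric(x$bias$visit_weights)
  )
}

#' Glance at an AWH sampling result
#'
#' @param x An `awh_result`.
#' @param ... Unused.
#' @return A one-row tibble summarising the run: stage, histogram size,
#'   covering events, samples, walkers and simulated time.
#' @export
glance.awh_result <- function(x, ...) {
  tibble(
    stage = x$bias$stage,
    N = x$bias$N,
    N0 = x$bias$N0,
    covering_count = x$bias$covering_count,
    total_samples = x$bias$total_samples,
    n_updates = x$metadata$n_updates,
    n_walkers = length(x$metadata$seeds),
    time_per_walker_ps = x$metadata$time_per_walker_ps,
    total_time_ps = x$metadata$total_time_ps
  )
}

#' Tidy a permeability result
#'
#' Broom-style long form: one row per reported quantity with its standard
#' error where available.
#'
#' @param x A `permeability_result`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `unit`.
#' @export
tidy.permeability_result <- function(x, ...) {
  tibble(
    term = c("n_layers", "R_total", "K_P", "log10_KP"),
    estimate = c(x$n_layers$mean, x$R, x$K_P, x$log10_KP),
    std.error = c(x$n_layers$se, NA_real_, NA_real_, x$se_log10_KP),
    unit = c("bilayers", "h/cm", "cm/h", "log10(cm/h)")
  )
}

#' Glance at a permeability result
#'
#' @param x A `permeability_result`.
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities.
#' @export
glance.permeability_result <- function(x, ...) {
  tibble(
    R_h_per_cm = x$R,
    K_P_cm_per_h = x$K_P,
    log10_KP = x$log10_KP,
    se_log10_KP = x$se_log10_KP,
    n_layers = x$n_layers$mean,
    n_layers_se = x$n_layers$se
  )
}

#' Tidy a solvation run
#'
#' @param x A `solvation_run`.
#' @param ... Unused.
#' @return A one-row tibble with the solvation free energy and run
#'   bookkeeping.
#' @export
tidy.solvation_run <- function(x, ...) {
  tibble(
    term = "dG_solv",
    estimate = x$dG_solv,
    std.error = x$se,
    unit = "kJ/mol",
    converged = x$converged,
    n_walkers = x$metadata$n_walkers,
    time_per_walker_ps = x$metadata$time_per_walker_ps,
    total_time_ps = x$metadata$total_time_ps
  )
}
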