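#' Assemble a bias-force time series
#'
#' Validates and tags the per-walker time series of the instantaneous
#' umbrella (bias) force used by the friction metric: columns `walker`,
#' `t` (ps, uniformly spaced per walker), `force` (kJ/mol/nm), `z_bin`
#' (assigned spatial bin = the walker's reference bin) and `lambda_index`.
#' [run_awh()] produces this tibble directly in `$force_series`.
#'
#' @param df A data frame with the columns above (`lambda_index` defaults
#'   to 1 if absent).
#' @return A `force_series` tibble.
#' @export
force_series <- function(df) {
  df <- as_tibble(df)
  if (!"walker" %in% names(df)) df$walker <- 1L
  if (!"lambda_index" %in% names(df)) df$lambda_index <- 1L
  need <- c("walker", "t", "force", "z_bin", "lambda_index")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_validation(paste0("force series lacks columns: ",
                            paste(miss, collapse = ", ")))
  }
  for (w in unique(df$walker)) {
    dt <- diff(df$t[df$walker == w])
    if (length(dt) && (max(dt) - min(dt)) > 1e-9) {
      abort_validation(sprintf("walker %s time spacing is not uniform", w))
    }
  }
  class(df) <- unique(c("force_series", class(df)))
  df
}

#' Friction metric from the bias-force autocorrelation
#'
#' Estimates the position-dependent friction `g(z)` from the blocked
#' time-integral of the bias-force autocovariance, conditioned on spatial
#' bin occupancy and computed separately for each walker:
#' `g(z) = beta^2 * I(z)` with
#' `I(z) = sum_b s_b(z)^2 / (2 sum_b T_b(z))`, where within each of
#' `n_blocks` contiguous time blocks `s_b(z)` is the time-integrated force
#' fluctuation collected while the walker's reference bin was `z` and
#' `T_b(z)` the occupancy time. The whole series - including the initial
#' stage - contributes by default; restrict with `t_min`.
#' The normalization is fixed by the Einstein relation `D(z) = 1/g(z)`
#' recovering the free diffusion coefficient `kT/(gamma m)` on a flat
#' landscape.
#'
#' Bins whose autocovariance integral is indistinguishable from the
#' white-noise measurement floor (`beta^2 dt var(F)/2`) are flagged
#' `low_info`.
#'
#' @param series A [force_series()] (or the `$force_series` of an
#'   [run_awh()] result).
#' @param grid The [awh_grid()] of the run.
#' @param n_blocks Number of autocorrelation blocks (default 128).
#' @param thermo A [thermo_params()].
#' @param lambda_index Only samples taken at this lambda state enter
#'   (default 1, fully coupled).
#' @param t_min Drop samples before this time (ps); default 0 keeps the
#'   initial stage, the production convention.
#' @return A `friction_profile` tibble: `walker`, `z_bin`, `z`, `g`
#'   (units such that `1/g` is nm^2/ps), `occupancy_ps`, `n_samples`,
#'   `low_info`; unsampled bins appear with `NA`, never zero.
#' @export
accumulate_friction <- function(series, grid, n_blocks = 128,
                                thermo = thermo_params(), lambda_index = 1,
                                t_min = 0) {
  if (!inherits(series, "force_series")) series <- force_series(series)
  stopifnot(inherits(grid, "awh_grid"))
  beta <- thermo$beta
  series <- dplyr::filter(series, .data$t >= t_min)
  if (!nrow(series)) abort_validation("no force samples after t_min")
  # sampling interval and block boundaries come from the full per-walker
  # series; filtering to one lambda state leaves gaps, not a coarser clock
  raw_meta <- series |>
    dplyr::group_by(.data$walker) |>
    dplyr::summarise(dt_s = (max(.data$t) - min(.data$t)) /
                       pmax(dplyr::n() - 1L, 1L),
                     t0 = min(.data$t), t1 = max(.data$t),
                     n_raw = dplyr::n(), .groups = "drop")
  series <- dplyr::filter(series, .data$lambda_index == !!lambda_index)
  if (!nrow(series)) abort_validation("no force samples at that lambda state")

  out <- series |>
    dplyr::group_by(.data$walker) |>
    dplyr::group_modify(function(d, key) {
      meta <- raw_meta[raw_meta$walker == key$walker, ]
      if (meta$n_raw < 4L * n_blocks) {
        abort_validation(sprintf(
          "walker series too short for %d blocks (%d samples)", n_blocks,
          meta$n_raw))
      }
      dt <- meta$dt_s
      t_block <- (meta$t1 - meta$t0 + dt) / n_blocks
      d$block <- pmin(floor((d$t - meta$t0) / t_block), n_blocks - 1)
      d |>
        dplyr::group_by(.data$z_bin) |>
        dplyr::group_modify(function(db, kb) {
          fbar <- mean(db$force)
          s <- tapply((db$force - fbar) * dt, db$block, sum)
          occ <- tapply(rep(dt, nrow(db)), db$block, sum)
          integral <- sum(s^2) / (2 * sum(occ))
          floor_val <- beta^2 * dt * var(db$force) / 2
          tibble(g = beta^2 * integral,
                 occupancy_ps = sum(occ),
                 n_samples = nrow(db),
                 low_info = !is.finite(floor_val) ||
                   (beta^2 * integral) < 5 * floor_val)
        }) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup()

  # complete to the full grid; unsampled bins flagged missing (NA)
  full <- tidyr::expand_grid(walker = unique(series$walker),
                             z_bin = seq_len(grid$n_z))
  out <- dplyr::left_join(full, out, by = c("walker", "z_bin"))
  out$z <- grid$z[out$z_bin]
  out <- dplyr::select(out, "walker", "z_bin", "z", "g", "occupancy_ps",
                       "n_samples", "low_info")
  class(out) <- unique(c("friction_profile", class(out)))
  attr(out, "n_blocks") <- n_blocks
  attr(out, "beta") <- beta
  attr(out, "lambda_index") <- lambda_index
  out
}

#' Convert a friction profile to a diffusion profile
#'
#' Einstein relation `D(z) = 1/g(z)`, elementwise per walker and bin;
#' missing bins propagate as missing.
#'
#' @param fp A `friction_profile` from [accumulate_friction()].
#' @return A tibble like `fp` with a `D` column (nm^2/ps).
#' @export
to_diffusion <- function(fp) {
  stopifnot(inherits(fp, "friction_profile"))
  bad <- which(!is.na(fp$g) & fp$g <= 0)
  if (length(bad)) {
    abort_validation(paste0("non-positive friction at bins: ",
                            paste(unique(fp$z_bin[bad]), collapse = ", ")))
  }
  fp$D <- 1 / fp$g
  fp
}

#' Combine per-walker friction profiles into one diffusion profile
#'
#' The friction metric is not communicated between walkers, so the diffusion
#' coefficient is computed separately per walker and the cross-walker spread
#' provides the uncertainty from a single set of simulations. Walker
#' profiles are combined on the friction scale (per-bin mean of `g`), the
#' combined diffusion is its inverse, and the SE is the standard error of
#' the per-walker `1/g` values. Bins sampled by a single walker keep their
#' value with `se = NA`.
#'
#' @param fp A `friction_profile` with >= 2 walkers (a list of single-walker
#'   profiles on a common grid is also accepted).
#' @return A [diffusion_profile()] with attribute `"n_walkers"` per bin kept
#'   in column `n_walkers`.
#' @export
combine_walkers <- function(fp) {
  if (is.list(fp) && !inherits(fp, "data.frame")) {
    zs <- lapply(fp, function(p) p$z_bin)
    if (length(unique(vapply(zs, length, integer(1)))) != 1 ||
        !all(vapply(zs, identical, logical(1), zs[[1]]))) {
      abort_validation("walker profiles are not on a common grid")
    }
    fp2 <- dplyr::bind_rows(fp)
    class(fp2) <- unique(c("friction_profile", class(fp2)))
    fp <- fp2
  }
  stopifnot(inherits(fp, "friction_profile"))
  n_walkers_total <- length(unique(fp$walker))
  if (n_walkers_total < 2) {
    warn("fewer than 2 walkers: no cross-walker uncertainty available")
  }
  comb <- fp |>
    dplyr::filter(!is.na(.data$g)) |>
    dplyr::group_by(.data$z_bin, .data$z) |>
    dplyr::summarise(
      g_mean = mean(.data$g),
      n_walkers = dplyr::n(),
      se_D = if (dplyr::n() >= 2) sd(1 / .data$g) / sqrt(dplyr::n())
             else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$z_bin)
  all_bins <- sort(unique(fp$z_bin))
  full <- tibble(z_bin = all_bins,
                 z = fp$z[match(all_bins, fp$z_bin)])
  comb <- dplyr::left_join(full, comb, by = c("z_bin", "z"))
  out <- diffusion_profile(comb$z, ifelse(is.na(comb$g_mean), NA,
                                          1 / comb$g_mean),
                           se = comb$se_D)
  out$n_walkers <- ifelse(is.na(comb$n_walkers), 0L, comb$n_walkers)
  out
}

#' Rolling median filter for diffusion profiles
#'
#' Reduces the noise of the local diffusion coefficient with a centered
#' rolling median of the given width; windows are truncated at the profile
#' edges. Single-bin spikes narrower than half the window vanish exactly and
#' monotone profiles stay monotone.
#'
#' @param dp A [diffusion_profile()].
#' @param window Window width in nm (default 0.2); must be at least the grid
#'   spacing.
#' @return The filtered profile, with filter metadata in attribute
#'   `"filter"`.
#' @export
rolling_median <- function(dp, window = 0.2) {
  stopifnot(inherits(dp, "diffusion_profile"))
  spacing <- min(diff(dp$z))
  if (window < spacing - 1e-12) {
    abort_validation("`window` must be at least the grid spacing")
  }
  half <- window / 2
  D <- vapply(seq_len(nrow(dp)), function(i) {
    sel <- abs(dp$z - dp$z[i]) <= half + 1e-12
    v <- dp$D[sel]
    if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  }, numeric(1))
  out <- dp
  out$D <- D
  attr(out, "filter") <- list(type = "rolling_median", window_nm = window)
  out
}
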