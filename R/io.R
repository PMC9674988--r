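#' Write a profile to xvg-style text
#'
#' Profiles are exchanged as plain text: `#` comment lines carrying a
#' versioned header (type, units, reference tag, filter metadata), optional
#' `@`-style plotting metadata lines, then whitespace-separated columns
#' (z in nm, value, optional SE). Values are written at full double
#' precision so read-write round trips are exact.
#'
#' @param x A [pmf_profile()] or [diffusion_profile()].
#' @param path Output file path.
#' @param comments Optional extra comment lines (written verbatim after the
#'   header, each prefixed with `# ` unless already starting with `#` or
#'   `@`).
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path, comments = NULL) {
  is_pmf <- inherits(x, "pmf_profile")
  is_dp <- inherits(x, "diffusion_profile")
  if (!is_pmf && !is_dp) {
    abort_validation("write_profile handles pmf_profile or diffusion_profile")
  }
  type <- if (is_pmf) "pmf" else "diffusion"
  val <- if (is_pmf) x$dG else x$D
  header <- c(
    "# awhperm profile format v1",
    sprintf("# type: %s", type),
    sprintf("# units: z nm, value %s, se %s",
            if (is_pmf) "kJ/mol" else "nm^2/ps",
            if (is_pmf) "kJ/mol" else "nm^2/ps")
  )
  if (is_pmf) {
    header <- c(header, sprintf("# reference: %s", attr(x, "reference_tag")))
  }
  filt <- attr(x, "filter")
  if (!is.null(filt)) {
    header <- c(header, sprintf("# filter: %s window=%g nm",
                                filt$type, filt$window_nm))
  }
  if (!is.null(comments)) {
    pre <- ifelse(grepl("^[#@]", comments), comments, paste("#", comments))
    header <- c(header, pre)
  }
  header <- c(header,
              sprintf('@ xaxis label "z (nm)"'),
              sprintf('@ yaxis label "%s"',
                      if (is_pmf) "dG (kJ/mol)" else "D (nm^2/ps)"))
  has_se <- "se" %in% names(x) && !all(is.na(x$se))
  rows <- if (has_se) {
    sprintf("%.17g %.17g %.17g", x$z, val, ifelse(is.na(x$se), NaN, x$se))
  } else {
    sprintf("%.17g %.17g", x$z, val)
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an xvg-style profile file
#'
#' Parses the text format written by [write_profile()] (and plain
#' two/three-column xvg-like files): `#`/`@` lines are treated as header and
#' preserved in the `"header"` attribute, the remaining lines must hold 2 or
#' 3 numeric columns with a strictly increasing first column. The profile
#' type is taken from the `# type:` header line (`pmf` assumed otherwise).
#'
#' @param path File to read.
#' @param type Override the profile type: `"auto"`, `"pmf"` or
#'   `"diffusion"`.
#' @return A [pmf_profile()] or [diffusion_profile()] with the original
#'   header lines in attribute `"header"`.
#' @export
read_profile <- function(path, type = c("auto", "pmf", "diffusion")) {
  type <- match.arg(type)
  if (!file.exists(path)) {
    abort_validation(sprintf("no such profile file: %s", path))
  }
  lines <- readLines(path)
  is_hdr <- grepl("^\\s*[#@]", lines) | !nzchar(trimws(lines))
  header <- lines[is_hdr & nzchar(trimws(lines))]
  data_lines <- which(!is_hdr)
  if (!length(data_lines)) {
    abort_validation(sprintf("%s: no data rows", path))
  }
  parsed <- lapply(data_lines, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2 || length(vals) > 3 || any(is.na(vals) & fields != "NaN")) {
      abort_validation(sprintf("%s:%d: expected 2 or 3 numeric columns", path, i))
    }
    vals
  })
  ncols <- vapply(parsed, length, integer(1))
  if (length(unique(ncols)) != 1) {
    abort_validation(sprintf("%s: inconsistent column counts", path))
  }
  m <- do.call(rbind, parsed)
  z <- m[, 1]
  if (any(diff(z) <= 0)) {
    bad <- data_lines[which(diff(z) <= 0)[1] + 1L]
    abort_validation(sprintf("%s:%d: grid is not strictly increasing", path, bad))
  }
  se <- if (ncol(m) == 3) ifelse(is.nan(m[, 3]), NA_real_, m[, 3]) else NULL
  if (type == "auto") {
    tline <- grep("^#\\s*type:", header, value = TRUE)
    type <- if (length(tline) && grepl("diffusion", tline[1])) "diffusion"
            else "pmf"
  }
  out <- if (type == "diffusion") {
    diffusion_profile(z, m[, 2], se = se)
  } else {
    rline <- grep("^#\\s*reference:", header, value = TRUE)
    ref <- if (length(rline) && grepl("vacuum", rline[1])) "vacuum" else "solvent"
    pmf_profile(z, m[, 2], se = se, reference = ref)
  }
  attr(out, "header") <- header
  out
}

#' Read a structured run configuration
#'
#' YAML configuration with sections `landscape`, `awh`, `friction`,
#' `permeability` (layer model), `solvation` and `seeds`; missing sections
#' fall back to package defaults. The `landscape` section is passed to
#' [build_landscape()] (with `barriers`/`wells` given as lists of records),
#' `awh` to [awh_config()], `permeability$layers` to [layer_model()].
#'
#' @param path YAML file.
#' @return A list with elements `landscape` (a `toy_landscape`), `awh`
#'   (an `awh_config`), `grid` (an `awh_grid` or NULL), `friction`,
#'   `layer_model`, `solvation`, `seeds`, and the `raw` parsed list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("no such config file: %s", path))
  }
  raw <- yaml::read_yaml(path)

  land_spec <- raw$landscape %||% list()
  for (nm in c("barriers", "wells")) {
    if (!is.null(land_spec[[nm]])) {
      land_spec[[nm]] <- dplyr::bind_rows(lapply(land_spec[[nm]], as.data.frame))
    }
  }
  if (!is.null(land_spec$schedule)) {
    land_spec$schedule <- lambda_schedule(land_spec$schedule$n_states %||% 21)
  }
  if (!is.null(land_spec$softcore)) {
    land_spec$softcore <- do.call(softcore_params, land_spec$softcore)
  }
  landscape <- build_landscape(land_spec)

  awh <- do.call(awh_config, raw$awh %||% list())
  grid <- NULL
  if (!is.null(raw$grid)) {
    g <- raw$grid
    grid <- awh_grid(z_min = g$z_min %||% 0,
                     z_max = g$z_max %||% landscape$L,
                     z_spacing = g$z_spacing %||% 0.05,
                     n_lambda = g$n_lambda %||% landscape$schedule$n_states)
  }
  lm <- do.call(layer_model, (raw$permeability %||% list())$layers %||% list())
  list(landscape = landscape, awh = awh, grid = grid,
       friction = raw$friction %||% list(n_blocks = 128),
       layer_model = lm,
       solvation = raw$solvation %||% list(),
       seeds = raw$seeds %||% NULL,
       raw = raw)
}

#' Write run metadata as JSON
#'
#' Serializes reproducibility metadata (seeds, covering events, stage
#' transitions, histogram growth, sample counts) next to a run's outputs.
#'
#' @param x A named list, or an `awh_result` / `solvation_run` /
#'   `permeability_result` (converted via their metadata).
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(x, path) {
  meta <- if (inherits(x, "awh_result")) {
    c(x$metadata, list(stage = x$bias$stage, N = x$bias$N))
  } else if (inherits(x, "solvation_run")) {
    c(x$metadata, list(dG_solv = x$dG_solv, converged = x$converged))
  } else if (inherits(x, "permeability_result")) {
    list(R_h_per_cm = x$R, K_P_cm_per_h = x$K_P, log10_KP = x$log10_KP,
         se_log10_KP = x$se_log10_KP, n_layers = x$n_layers)
  } else {
    x
  }
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
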