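#' Thermodynamic parameters
#'
#' Fixes the simulation temperature and the derived inverse thermal energy
#' `beta = 1 / (kB T)` used throughout the package, in particular in the
#' resistance integral `R = integral exp(beta dG(z)) / D(z) dz`.
#'
#' @param temperature Temperature in kelvin. Default 305.15 K (skin surface
#'   temperature used for all free-energy and permeability calculations).
#' @return An object of class `thermo_params`: a list with `temperature`
#'   (K), `kT` (kJ/mol) and `beta` (mol/kJ).
#' @examples
#' th <- thermo_params()
#' th$beta * th$kT  # 1
#' @export
thermo_params <- function(temperature = 305.15) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    abort_validation("`temperature` must be a single positive finite number")
  }
  kT <- KB_KJMOL * temperature
  structure(
    list(temperature = temperature, kT = kT, beta = 1 / kT),
    class = "thermo_params"
  )
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("<thermo_params> T = %.2f K, kT = %.6f kJ/mol, beta = %.6f mol/kJ\n",
              x$temperature, x$kT, x$beta))
  invisible(x)
}
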