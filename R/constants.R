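#' Physical constants
#'
#' CODATA values used throughout the package. The gas constant is expressed
#' in cal/(mol K) because activation and unfolding energetics are reported in
#' calorie units in this field.
#'
#' @return Named list with elements `R_cal` (gas constant, cal/(mol K)),
#'   `R_J` (J/(mol K)), `kB` (Boltzmann constant, J/K), `h` (Planck
#'   constant, J s) and `N_A` (Avogadro number, 1/mol).
#' @export
#' @examples
#' physical_constants()$R_cal
physical_constants <- function() {
  list(
    R_cal = 8.31446261815324 / 4.184,
    R_J   = 8.31446261815324,
    kB    = 1.380649e-23,
    h     = 6.62607015e-34,
    N_A   = 6.02214076e23
  )
}

.const <- physical_constants()

#' Convert between Celsius and Kelvin
#'
#' @param t Temperature in degrees Celsius.
#' @param T Temperature in Kelvin.
#' @return Numeric temperature in the other scale.
#' @export
celsius_to_kelvin <- function(t) t + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(T) T - 273.15

#' Convert a concentration with unit suffix to mol/L
#'
#' Internally all concentrations are mol/L; user-facing tables may carry
#' mM, uM (or the unicode micro sign) and nM.
#'
#' @param x Numeric concentration values.
#' @param unit One of `"M"`, `"mM"`, `"uM"`, `"nM"` (also accepts
#'   `"µM"`/`"μM"`).
#' @return Concentration in mol/L.
#' @export
to_molar <- function(x, unit = "M") {
  fac <- switch(unit,
    "M" = 1, "mM" = 1e-3, "uM" = 1e-6, "µM" = 1e-6, "μM" = 1e-6,
    "nM" = 1e-9,
    stop("unknown concentration unit: ", unit)
  )
  x * fac
}
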