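# Atomic constants embedded in source so results never depend on an external
# resource. Exact masses and natural abundances follow the IUPAC 2013
# compilation; "D" is the isotopically pure deuterium label and carries no
# natural-abundance mixture.

.ELECTRON_MASS <- 0.000548579909

.ISOTOPE_TABLE <- list(
  H  = list(mass = c(1.00782503207, 2.01410177785), abundance = c(0.999885, 0.000115)),
  D  = list(mass = 2.01410177785,                   abundance = 1),
  C  = list(mass = c(12, 13.00335483507),           abundance = c(0.9893, 0.0107)),
  N  = list(mass = c(14.00307400443, 15.00010889888), abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.99491461957, 16.99913175650, 17.99915961286),
            abundance = c(0.99757, 0.00038, 0.00205)),
  F  = list(mass = 18.99840316273,                  abundance = 1),
  Na = list(mass = 22.98976928,                     abundance = 1),
  Si = list(mass = c(27.97692653465, 28.97649466490, 29.973770136),
            abundance = c(0.92223, 0.04685, 0.03092)),
  P  = list(mass = 30.97376199842,                  abundance = 1),
  S  = list(mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Cl = list(mass = c(34.968852682, 36.965902602),   abundance = c(0.7576, 0.2424)),
  K  = list(mass = c(38.9637064864, 39.963998166, 40.9618252579),
            abundance = c(0.932581, 0.000117, 0.067302)),
  Br = list(mass = c(78.9183376, 80.9162897),       abundance = c(0.5069, 0.4931)),
  I  = list(mass = 126.9044719,                     abundance = 1)
)

# Conventional (average) atomic weights, used only for gravimetric
# ng <-> pmol conversion of weighed material.
.AVERAGE_WEIGHTS <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Br = 79.904, I = 126.904
)

#' Isotope table for one element
#'
#' Returns the exact masses (Da) and natural abundance fractions of the
#' isotopes of an element, as embedded in the package. Abundances sum to 1;
#' masses are strictly increasing.
#'
#' @param symbol Element symbol (e.g. `"C"`); `"D"` is pure deuterium.
#' @return A list with numeric vectors `mass` and `abundance`.
#' @export
#' @examples
#' element_isotopes("C")
element_isotopes <- function(symbol) {
  tab <- .ISOTOPE_TABLE[[symbol]]
  if (is.null(tab)) {
    stop("unknown element symbol: '", symbol, "'", call. = FALSE)
  }
  tab
}
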