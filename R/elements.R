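# Bundled stable-isotope masses and natural abundances (IUPAC/NIST standard
# values). Masses in dalton, abundances as fractions summing to 1 per element,
# isotopes ordered by increasing mass (the first isotope of each element is the
# one used for monoisotopic masses).

.isotope_data <- list(
  H  = list(mass = c(1.0078250319, 2.0141017779),
            abundance = c(0.999885, 0.000115)),
  B  = list(mass = c(10.0129370, 11.0093055),
            abundance = c(0.199, 0.801)),
  C  = list(mass = c(12.0, 13.0033548378),
            abundance = c(0.9893, 0.0107)),
  N  = list(mass = c(14.0030740052, 15.0001088984),
            abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146221, 16.9991315, 17.9991604),
            abundance = c(0.99757, 0.00038, 0.00205)),
  F  = list(mass = 18.9984032, abundance = 1),
  Na = list(mass = 22.98976928, abundance = 1),
  Mg = list(mass = c(23.9850417, 24.98583702, 25.98259304),
            abundance = c(0.7899, 0.1000, 0.1101)),
  Si = list(mass = c(27.9769265327, 28.97649472, 29.97377022),
            abundance = c(0.92223, 0.04685, 0.03092)),
  P  = list(mass = 30.97376151, abundance = 1),
  S  = list(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Cl = list(mass = c(34.96885271, 36.96590260),
            abundance = c(0.7576, 0.2424)),
  K  = list(mass = c(38.9637069, 39.96399867, 40.96182597),
            abundance = c(0.932581, 0.000117, 0.067302)),
  Ca = list(mass = c(39.9625912, 41.9586183, 42.9587668, 43.9554811,
                     45.9536928, 47.952534),
            abundance = c(0.96941, 0.00647, 0.00135, 0.02086, 0.00004, 0.00187)),
  Se = list(mass = c(73.9224766, 75.9192141, 76.9199146, 77.9173095,
                     79.9165218, 81.9167000),
            abundance = c(0.0089, 0.0937, 0.0763, 0.2377, 0.4961, 0.0873)),
  Br = list(mass = c(78.9183376, 80.916291),
            abundance = c(0.5069, 0.4931)),
  I  = list(mass = 126.904468, abundance = 1)
)

#' Bundled element isotope table
#'
#' Stable-isotope masses and natural abundances for the chemical elements
#' supported by [parse_formula()] and [theoretical_pattern()]. Values are the
#' IUPAC/NIST standard atomic data; isotopes are ordered by increasing mass and
#' abundances sum to one per element.
#'
#' @return A tibble with columns `element`, `isotope_mass` (dalton) and
#'   `abundance` (fraction).
#' @examples
#' isotope_table()
#' @export
isotope_table <- function() {
  tibble::tibble(
    element = rep(names(.isotope_data),
                  vapply(.isotope_data, function(x) length(x$mass), integer(1))),
    isotope_mass = unlist(lapply(.isotope_data, `[[`, "mass"), use.names = FALSE),
    abundance = unlist(lapply(.isotope_data, `[[`, "abundance"), use.names = FALSE)
  )
}

# m/z distance between successive isotope peaks at charge 1:
# mass(13C) - mass(12C), the dominant isotope spacing in biological samples.
.delta_m <- 1.003355

#' Expected m/z spacing of isotope peaks
#'
#' The mass difference between successive isotope peaks is approximated by the
#' 13C-12C mass difference (1.003355 Da), divided by the charge state.
#'
#' @param z Charge state (integer >= 1).
#' @param i Isotope number (integer >= 1); the i-th isotope peak lies
#'   `i * 1.003355 / z` above the monoisotopic peak in m/z.
#' @return m/z shift in dalton.
#' @examples
#' isotope_mz_shift(1, 1)  # 1.003355
#' isotope_mz_shift(2, 3)
#' @export
isotope_mz_shift <- function(z, i) {
  if (any(z < 1) || any(i < 1)) {
    stop("charge `z` and isotope number `i` must both be >= 1", call. = FALSE)
  }
  i * .delta_m / z
}
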