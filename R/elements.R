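# Atomic constants used by the 2D descriptor engine. Values are the standard
# physical-constant parametrizations used throughout the 2D-QSAR literature:
# IUPAC standard/monoisotopic masses, Bondi van der Waals radii (volume =
# 4/3*pi*r^3), Sanderson / Pauling / Allred-Rochow electronegativities,
# atomic polarizabilities (1994 compilation), NIST first ionization energies
# (eV), and McGowan characteristic volumes (cm^3/mol / 10).
# Covers the organic-subset elements handled by the SMILES reader.

.elementData <- local({
  df <- data.frame(
    elem    = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"),
    Z       = c(1L, 5L, 6L, 7L, 8L, 9L, 14L, 15L, 16L, 17L, 35L, 53L),
    # standard atomic weight (autocorrelation weight "m")
    mass    = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.9984032,
                28.085, 30.973762, 32.06, 35.45, 79.904, 126.90447),
    # monoisotopic mass (exact molecular weight)
    isomass = c(1.007825032, 11.0093054, 12.0, 14.003074, 15.99491462,
                18.99840322, 27.97692653, 30.97376163, 31.972071,
                34.96885268, 78.9183371, 126.904473),
    # van der Waals volume from Bondi radii
    vdwvol  = c(5.575279762570688, 29.64778792497513, 20.579526276115534,
                15.598531123848922, 14.710226951490485, 13.30578842767868,
                38.79238608652677, 24.429024474314232, 24.429024474314232,
                22.44929750377706, 26.521848780380633, 32.51503157531224),
    se      = c(2.592, 2.275, 2.746, 3.194, 3.654, 4.0,
                2.138, 2.515, 2.957, 3.475, 3.219, 2.778),
    pe      = c(2.2, 2.04, 2.55, 3.04, 3.44, 3.98,
                1.9, 2.19, 2.58, 3.16, 2.96, 2.66),
    are     = c(2.2, 2.01, 2.5, 3.07, 3.5, 4.1,
                1.74, 2.06, 2.44, 2.83, 2.74, 2.21),
    pol     = c(0.666793, 3.03, 1.67, 1.1, 0.802, 0.557,
                5.53, 3.63, 2.9, 2.18, 3.05, 5.35),
    ion     = c(13.598443, 8.29802, 11.2603, 14.5341, 13.61805, 17.4228,
                8.15168, 10.48669, 10.36001, 12.96763, 11.8138, 10.45126),
    period  = c(1L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 4L, 5L),
    nouter  = c(1L, 3L, 4L, 5L, 6L, 7L, 4L, 5L, 6L, 7L, 7L, 7L),
    mcgowan = c(8.71, 18.31, 16.35, 14.39, 12.43, 10.47,
                26.83, 24.87, 22.91, 20.95, 26.21, 34.54),
    # conventional atomic weights (mass-weighted information indices)
    atwt    = c(1.008, 10.812, 12.011, 14.007, 15.999, 18.998,
                28.086, 30.974, 32.067, 35.453, 79.904, 126.904),
    stringsAsFactors = FALSE
  )
  rownames(df) <- df$elem
  df
})

#' Look up an atomic constant for a vector of element symbols
#'
#' @param elem character vector of element symbols.
#' @param what column of the internal element table, e.g. "mass", "Z", "se".
#' @return numeric vector, NA for unknown elements.
#' @keywords internal
#' @noRd
.elemProp <- function(elem, what) {
  out <- .elementData[[what]][match(elem, .elementData$elem)]
  as.numeric(out)
}

# default SMILES valences; multi-valent elements list all allowed states
.defaultValences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, F = 1, Si = 4, P = c(3, 5),
  S = c(2, 4, 6), Cl = 1, Br = 1, I = 1
)

.halogens <- c("F", "Cl", "Br", "I")
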