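# Pinned atomic constants (IUPAC/CIAAW).  These are versioned package
# constants: all mass arithmetic in the package resolves to this table so
# results are reproducible across installations.

#' Monoisotopic atomic masses used by the package
#'
#' Named vector of monoisotopic (most abundant isotope) atomic masses in Da
#' for the elements handled by the package.  Pinned IUPAC/CIAAW values.
#'
#' @return Named numeric vector of masses in Da.
#' @export
#' @examples
#' atomic_masses()[["O"]]
atomic_masses <- function() .ATOMIC_MASSES

.ATOMIC_MASSES <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  P  = 30.97376151,
  Na = 22.98976928,
  K  = 38.9637064864
)

# Mass of a proton; singly protonated ions are assumed throughout.
.PROTON_MASS <- 1.007276466

# Isotope patterns per element: dn = extra neutron count relative to the
# most abundant isotope, offset = mass offset in Da, abundance = isotopic
# abundance.  Most-abundant isotope always first (dn = 0).
.ISOTOPES <- list(
  H = list(dn = c(0L, 1L),
           offset = c(0, 1.00627675),
           abundance = c(0.999885, 0.000115)),
  C = list(dn = c(0L, 1L),
           offset = c(0, 1.00335484),
           abundance = c(0.9893, 0.0107)),
  N = list(dn = c(0L, 1L),
           offset = c(0, 0.99703489),
           abundance = c(0.99636, 0.00364)),
  O = list(dn = c(0L, 1L, 2L),
           offset = c(0, 1.00421690, 2.00424490),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(dn = c(0L, 1L, 2L, 4L),
           offset = c(0, 0.99938780, 1.99579590, 3.99501000),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P = list(dn = 0L, offset = 0, abundance = 1),
  Na = list(dn = 0L, offset = 0, abundance = 1),
  K = list(dn = c(0L, 1L, 2L),
           offset = c(0, 0.99997000, 1.99812000),
           abundance = c(0.932581, 0.000117, 0.067302))
)

# Nucleobase substituents as bonded to the backbone acetyl linker (one H
# lost at the glycosidic nitrogen).
.BASE_SUBSTITUENT <- list(
  A = c(C = 5L, H = 4L, N = 5L),            # adenin-9-yl
  C = c(C = 4L, H = 4L, N = 3L, O = 1L),    # cytosin-1-yl
  G = c(C = 5L, H = 4L, N = 5L, O = 1L),    # guanin-9-yl
  T = c(C = 5L, H = 5L, N = 2L, O = 2L)     # thymin-1-yl
)

# aeg-PNA backbone repeating unit as incorporated in the chain (one amide
# bond formed, no free water): -NH-CH2-CH2-N(CO-CH2-Base)-CH2-CO-
# counted without the base substituent.
.AEG_BACKBONE <- c(C = 6L, H = 9L, N = 2L, O = 2L)

.BASES <- c("A", "C", "G", "T")
.COMP_MAP <- c(A = "T", C = "G", G = "C", T = "A", x = "x")
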