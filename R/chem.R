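# PNA oligomer chemistry: residue and termini tables, oligomer composition,
# isotope envelopes, MALDI adducts and the azide reversible-terminator delta.

#' Residue composition table for aeg-PNA
#'
#' Compositions of the four N-(2-aminoethyl)glycine (aeg) PNA residues as
#' incorporated in a chain (per amide bond formed, i.e. no free water), plus
#' serine-modified variants (lowercase letters) which differ from the aeg
#' residue of the same base by exactly one CH2O unit.  The table can be
#' overridden per call in [compose_oligomer()] or loaded from a YAML file
#' with [load_residue_table()].
#'
#' @return Named list of [ec()] compositions, keyed by residue letter
#'   (`A`, `C`, `G`, `T` and serine-modified `a`, `c`, `g`, `t`).
#' @export
#' @examples
#' monoisotopic_mass(pna_residues()$T)   # 266.1015
pna_residues <- function() {
  hit <- .iso_cache[["__pna_residues__"]]
  if (!is.null(hit)) return(hit)
  aeg <- lapply(.BASE_SUBSTITUENT, function(b) ec(.AEG_BACKBONE) + ec(b))
  ser <- lapply(aeg, function(r) r + ec(c(C = 1, H = 2, O = 1)))
  names(ser) <- tolower(names(aeg))
  out <- c(aeg, ser)
  .iso_cache[["__pna_residues__"]] <- out
  out
}

#' Monoisotopic residue masses
#'
#' @param residue_table Residue composition table, see [pna_residues()].
#' @return Named numeric vector of residue masses in Da.
#' @export
residue_masses <- function(residue_table = pna_residues()) {
  vapply(residue_table, monoisotopic_mass, numeric(1))
}

#' Load a residue/termini composition table from a YAML file
#'
#' The schema is a flat mapping from residue letter to formula string, e.g.
#' `T: C11H14N4O4`.  Entries replace or extend the built-in table.
#'
#' @param path Path to a YAML file.
#' @param base Table to extend (default [pna_residues()]).
#' @return Named list of [ec()] compositions.
#' @export
load_residue_table <- function(path, base = pna_residues()) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)))
    stop("residue table file must be a mapping residue -> formula",
         call. = FALSE)
  for (k in names(raw)) base[[k]] <- ec(as.character(raw[[k]]))
  base
}

#' Default biotin-linker composition for the primer C-terminus
#'
#' Synthetic stand-in for the biotin plus short hydrophilic spacer carried at
#' the primer C-terminus (biotin acyl + AEEA-type spacer + terminal amide).
#' Only its mass matters downstream, and it cancels in all ladder
#' differences; override it with any [ec()] composition when the true linker
#' structure is known.
#'
#' @return An [ec()] composition.
#' @export
default_biotin_linker <- function() ec("C16H28N4O5S")

.N_TERM_DELTA <- list(
  "free-amine" = list(add = c(H = 1), sub = NULL),
  "azide"      = list(add = c(N = 2), sub = c(H = 1)),
  "Fmoc"       = list(add = c(C = 15, H = 11, O = 2), sub = NULL),
  "acetyl"     = list(add = c(C = 2, H = 3, O = 1), sub = NULL)
)

.C_TERM_DELTA <- list(
  "free-acid"    = list(add = c(H = 1, O = 1), sub = NULL),
  "amide"        = list(add = c(N = 1, H = 2), sub = NULL),
  "linker-biotin" = NULL  # user-supplied linker composition
)

#' Terminus state of a PNA oligomer
#'
#' @param n_terminus One of `"free-amine"`, `"azide"`, `"Fmoc"`, `"acetyl"`.
#'   The azide is the reversible terminator; it differs from the free amine
#'   by a fixed N2-for-H2 composition delta (see [terminator_delta()]).
#' @param c_terminus One of `"amide"`, `"free-acid"`, `"linker-biotin"`.
#' @param linker_composition [ec()] composition of the C-terminal linker;
#'   required when `c_terminus = "linker-biotin"`.
#' @return A `termini_state` list.
#' @export
termini_state <- function(n_terminus = c("free-amine", "azide", "Fmoc", "acetyl"),
                          c_terminus = c("amide", "free-acid", "linker-biotin"),
                          linker_composition = NULL) {
  n_terminus <- match.arg(n_terminus)
  c_terminus <- match.arg(c_terminus)
  if (c_terminus == "linker-biotin") {
    if (is.null(linker_composition))
      stop("linker_composition is required for c_terminus = 'linker-biotin'",
           call. = FALSE)
    linker_composition <- ec(linker_composition)
  }
  structure(list(n_terminus = n_terminus, c_terminus = c_terminus,
                 linker_composition = linker_composition),
            class = "termini_state")
}

#' Exact neutral composition of a PNA oligomer
#'
#' Strictly additive: sum of residue compositions (sequence written C-to-N)
#' plus termini deltas plus `oxidations` extra oxygen atoms.
#'
#' @param sequence Residue letters C-to-N, as a single string or character
#'   vector.  Uppercase = aeg residues, lowercase = serine-modified.
#' @param termini A [termini_state()].
#' @param oxidations Non-negative integer count of +O modifications
#'   (biotin oxidation satellites observed at nominal +16 Da).
#' @param residue_table Residue composition table (default [pna_residues()]).
#' @return An [ec()] composition of the neutral molecule.
#' @export
#' @examples
#' t1 <- compose_oligomer("T", termini_state("free-amine", "free-acid"))
#' monoisotopic_mass(t1)   # aeg-T residue + H2O
compose_oligomer <- function(sequence,
                             termini = termini_state(),
                             oxidations = 0L,
                             residue_table = pna_residues()) {
  chars <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  if (length(chars) == 0L)
    stop("sequence must be non-empty", call. = FALSE)
  if (!inherits(termini, "termini_state"))
    stop("termini must be a termini_state object", call. = FALSE)
  if (oxidations < 0 || oxidations != round(oxidations))
    stop("oxidations must be a non-negative integer", call. = FALSE)
  unknown <- setdiff(unique(chars), names(residue_table))
  if (length(unknown) > 0L)
    stop("unknown residue(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  comp <- ec(NULL)
  tab <- table(factor(chars, levels = names(residue_table)))
  for (r in names(tab)[tab > 0])
    comp <- comp + residue_table[[r]] * as.integer(tab[[r]])
  nd <- .N_TERM_DELTA[[termini$n_terminus]]
  comp <- comp + ec(nd$add)
  if (!is.null(nd$sub)) comp <- comp - ec(nd$sub)
  if (termini$c_terminus == "linker-biotin") {
    comp <- comp + termini$linker_composition
  } else {
    cd <- .C_TERM_DELTA[[termini$c_terminus]]
    comp <- comp + ec(cd$add)
  }
  if (oxidations > 0) comp <- comp + ec(c(O = 1)) * as.integer(oxidations)
  comp
}

#' Mass delta of the azide-to-amine terminator reduction
#'
#' Staudinger reduction of the N-terminal azide cap to a free amine loses N2
#' and gains H2; the returned value is the signed mass change per reduction
#' event (about -25.9905 Da).
#'
#' @return Mass delta in Da (negative: the reduced species is lighter).
#' @export
terminator_delta <- function() {
  2 * .ATOMIC_MASSES[["H"]] - 2 * .ATOMIC_MASSES[["N"]]
}

#' m/z of a singly charged MALDI adduct
#'
#' All ions are assumed singly charged (linear positive-mode MALDI of short
#' PNA oligomers); supported adducts are M+H, M+Na and M+K.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct One of `"M+H"`, `"M+Na"`, `"M+K"`.
#' @return m/z in Da.
#' @export
#' @examples
#' adduct_mz(1000, "M+Na") - adduct_mz(1000, "M+H")  # 21.9819
adduct_mz <- function(neutral_mass, adduct = c("M+H", "M+Na", "M+K")) {
  if (!is.numeric(neutral_mass) || any(neutral_mass <= 0))
    stop("neutral_mass must be positive", call. = FALSE)
  adduct <- match.arg(adduct)
  shift <- switch(adduct,
    "M+H"  = 0,
    "M+Na" = .ATOMIC_MASSES[["Na"]] - .ATOMIC_MASSES[["H"]],
    "M+K"  = .ATOMIC_MASSES[["K"]] - .ATOMIC_MASSES[["H"]])
  neutral_mass + .PROTON_MASS + shift
}

#' Proton mass used for neutral-mass conversion
#' @return Proton mass in Da.
#' @export
proton_mass <- function() .PROTON_MASS

# --- isotope envelope -------------------------------------------------------

# Distributions are represented on an integer extra-neutron grid as a pair of
# vectors: A[k] = abundance in bin k-1 neutrons, M[k] = abundance-weighted
# sum of mass offsets.  Convolution is truncated at .ISO_BINS bins; the
# distribution is never renormalized after truncation, so abundances remain
# fractions of the untruncated total.
.ISO_BINS <- 31L

.iso_conv <- function(a, b, K = .ISO_BINS) {
  A <- numeric(K); M <- numeric(K)
  na <- min(length(a$A), K)
  for (i in seq_len(na)) {
    if (a$A[i] == 0 && a$M[i] == 0) next
    jmax <- min(length(b$A), K - i + 1L)
    if (jmax < 1L) break
    j <- seq_len(jmax)
    k <- i + j - 1L
    A[k] <- A[k] + a$A[i] * b$A[j]
    M[k] <- M[k] + a$M[i] * b$A[j] + a$A[i] * b$M[j]
  }
  list(A = A, M = M)
}

.iso_one_atom <- function(element) {
  iso <- .ISOTOPES[[element]]
  if (is.null(iso))
    stop("no isotope pattern registered for element: ", element,
         call. = FALSE)
  A <- numeric(.ISO_BINS); M <- numeric(.ISO_BINS)
  k <- iso$dn + 1L
  A[k] <- iso$abundance
  M[k] <- iso$abundance * iso$offset
  list(A = A, M = M)
}

# Memoised element^count polynomials (powers of two), shared across calls.
.iso_cache <- new.env(parent = emptyenv())

.iso_element_power <- function(element, n) {
  key <- paste0(element, ":", n)
  hit <- .iso_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (n == 1L) {
    out <- .iso_one_atom(element)
  } else {
    half <- n %/% 2L
    out <- .iso_conv(.iso_element_power(element, half),
                     .iso_element_power(element, n - half))
  }
  .iso_cache[[key]] <- out
  out
}

#' Isotope envelope of a composition
#'
#' Aggregated (per extra-neutron bin) isotope distribution computed by
#' stepwise polynomial convolution of the per-element isotope patterns.
#' Abundances are normalized to sum to 1 over the untruncated distribution
#' (tails beyond the internal bin limit are simply absent, never
#' renormalized away); offsets are abundance-weighted mean mass offsets per
#' bin and ascend in steps of about 1.003 Da for carbon-dominated species.
#'
#' @param composition An [ec()] composition.
#' @param max_peaks Maximum number of peaks returned (>= 1).
#' @return `data.frame` with columns `offset` (Da relative to the
#'   monoisotopic mass) and `abundance`.
#' @export
#' @examples
#' isotope_envelope(ec(c(C = 1)), 2)   # 0.9893 / 0.0107
isotope_envelope <- function(composition, max_peaks = 8L) {
  x <- ec(composition)
  if (max_peaks < 1L) stop("max_peaks must be >= 1", call. = FALSE)
  if (length(x) == 0L)
    return(data.frame(offset = 0, abundance = 1))
  acc <- NULL
  for (el in names(x)) {
    p <- .iso_element_power(el, as.integer(x[[el]]))
    acc <- if (is.null(acc)) p else .iso_conv(acc, p)
  }
  keep <- acc$A > 1e-15
  offset <- ifelse(keep, acc$M / pmax(acc$A, 1e-300), 0)
  out <- data.frame(offset = offset[keep], abundance = acc$A[keep])
  out <- out[order(out$offset), , drop = FALSE]
  utils::head(out, max_peaks)
}
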