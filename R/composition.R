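# Elemental compositions: exact integer atom counts.  All higher-level mass
# arithmetic (residues, termini, adducts, oxidation) reduces to this class,
# so masses are always derived from integer atom bookkeeping, never from
# cached floating-point sums.

#' Create an elemental composition
#'
#' An elemental composition is a named vector of non-negative integer atom
#' counts (e.g. `c(C = 11, H = 14, N = 4, O = 4)`).  Compositions support
#' `+`, `-` and integer `*`; subtraction that would drive any count negative
#' is an error, so compositions stay physically meaningful.
#'
#' @param x Named numeric vector of atom counts, a formula string such as
#'   `"C11H14N4O4"`, or an existing `elem_comp` object.  `NULL` or an empty
#'   string gives the empty composition.
#' @return An object of class `elem_comp`.
#' @export
#' @examples
#' ec("H2O")
#' ec(c(C = 1)) + ec("O2")
#' monoisotopic_mass(ec("H2O"))
ec <- function(x = NULL) {
  if (inherits(x, "elem_comp")) return(x)
  if (is.null(x) || (is.character(x) && !nzchar(x))) {
    counts <- integer(0)
  } else if (is.character(x)) {
    counts <- parse_formula(x)
  } else if (is.numeric(x)) {
    if (is.null(names(x)) && length(x) > 0L)
      stop("atom counts must be named by element symbol", call. = FALSE)
    counts <- x
  } else {
    stop("cannot interpret input as an elemental composition", call. = FALSE)
  }
  if (any(counts != round(counts)))
    stop("atom counts must be integers", call. = FALSE)
  if (any(counts < 0))
    stop("atom counts must be non-negative", call. = FALSE)
  counts <- counts[counts > 0]
  counts <- vapply(split(as.integer(counts), names(counts)), sum, integer(1))
  counts <- counts[order(names(counts))]
  structure(counts, class = "elem_comp")
}

#' Parse a molecular formula string
#'
#' @param formula Formula string, e.g. `"C10H16N2O3S"`.  Element symbols are
#'   one capital letter optionally followed by one lowercase letter; counts
#'   default to 1.
#' @return Named integer vector of atom counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("[[:space:]]", "", formula)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (length(tokens) == 0L || sum(attr(m, "match.length")) != nchar(s))
    stop("malformed formula: ", formula, call. = FALSE)
  el <- sub("[0-9]*$", "", tokens)
  n <- sub("^[A-Z][a-z]?", "", tokens)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  names(n) <- el
  n
}

#' @export
format.elem_comp <- function(x, ...) {
  if (length(x) == 0L) return("(empty)")
  el <- names(x)
  ord <- c(intersect(c("C", "H"), el), setdiff(sort(el), c("C", "H")))
  paste0(ord, ifelse(x[ord] == 1L, "", x[ord]), collapse = "")
}

#' @export
print.elem_comp <- function(x, ...) {
  cat("<elem_comp> ", format(x), "  (", sprintf("%.4f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' @export
Ops.elem_comp <- function(e1, e2) {
  op <- .Generic
  if (op == "*") {
    comp <- if (inherits(e1, "elem_comp")) e1 else e2
    k <- if (inherits(e1, "elem_comp")) e2 else e1
    if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 0)
      stop("compositions can only be multiplied by a non-negative integer",
           call. = FALSE)
    return(ec(unclass(comp) * as.integer(k)))
  }
  if (!op %in% c("+", "-"))
    stop("operation '", op, "' not defined for elemental compositions",
         call. = FALSE)
  a <- ec(e1); b <- ec(e2)
  el <- union(names(a), names(b))
  av <- structure(integer(length(el)), names = el)
  bv <- av
  av[names(a)] <- a
  bv[names(b)] <- b
  out <- if (op == "+") av + bv else av - bv
  if (any(out < 0))
    stop("composition subtraction would give a negative count for: ",
         paste(el[out < 0], collapse = ", "), call. = FALSE)
  ec(out)
}

#' Monoisotopic mass of a composition
#'
#' Sum over atoms of the most-abundant-isotope atomic masses from the pinned
#' constant table.  Linear in the composition.
#'
#' @param composition An [ec()] composition (or anything coercible to one).
#' @return Mass in Da (0 for the empty composition).
#' @export
monoisotopic_mass <- function(composition) {
  x <- ec(composition)
  if (length(x) == 0L) return(0)
  unknown <- setdiff(names(x), names(.ATOMIC_MASSES))
  if (length(unknown) > 0L)
    stop("no atomic mass registered for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sum(.ATOMIC_MASSES[names(x)] * as.numeric(x))
}
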