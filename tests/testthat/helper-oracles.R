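# Independent oracles used across the suite.  These deliberately avoid the
# package's own composition/envelope code paths.

# IUPAC monoisotopic masses, re-entered independently of the package table.
oracle_masses <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069,
                   Na = 22.98976928, K = 38.9637064864)

oracle_mass <- function(counts) {
  sum(oracle_masses[names(counts)] * as.numeric(counts))
}

# Atom-count oracle for the aeg-PNA residues: every structural group of the
# drawn residue (-NH-CH2-CH2-N(CO-CH2-Base)-CH2-CO-) tallied separately.
oracle_residue_counts <- function(base) {
  groups <- list(
    nh  = c(N = 1, H = 1),      # backbone secondary amine
    ch2_a = c(C = 1, H = 2),    # aminoethyl CH2
    ch2_b = c(C = 1, H = 2),    # aminoethyl CH2
    n_tert = c(N = 1),          # tertiary backbone nitrogen
    ch2_gly = c(C = 1, H = 2),  # glycine CH2
    co_acyl = c(C = 1, O = 1),  # backbone carbonyl
    co_link = c(C = 1, O = 1),  # base-acetyl linker carbonyl
    ch2_link = c(C = 1, H = 2), # base-acetyl linker CH2
    base = switch(base,
      A = c(C = 5, H = 4, N = 5),          # adenin-9-yl
      C = c(C = 4, H = 4, N = 3, O = 1),   # cytosin-1-yl
      G = c(C = 5, H = 4, N = 5, O = 1),   # guanin-9-yl
      T = c(C = 5, H = 5, N = 2, O = 2)))  # thymin-1-yl
  out <- c(C = 0, H = 0, N = 0, O = 0)
  for (g in groups) for (el in names(g)) out[el] <- out[el] + g[[el]]
  out
}

# Exhaustive isotopologue enumeration for small molecules: every way of
# distributing each element's atoms over its isotopes, with multinomial
# weights, aggregated by total extra-neutron count.
oracle_isotopes <- list(
  H = list(dn = c(0, 1), off = c(0, 1.00627675), ab = c(0.999885, 0.000115)),
  C = list(dn = c(0, 1), off = c(0, 1.00335484), ab = c(0.9893, 0.0107)),
  N = list(dn = c(0, 1), off = c(0, 0.99703489), ab = c(0.99636, 0.00364)),
  O = list(dn = c(0, 1, 2), off = c(0, 1.0042169, 2.0042449),
           ab = c(0.99757, 0.00038, 0.00205)),
  S = list(dn = c(0, 1, 2, 4), off = c(0, 0.9993878, 1.9957959, 3.99501),
           ab = c(0.9499, 0.0075, 0.0425, 0.0001)))

# all compositions of n into k non-negative parts
.compositions_of <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- NULL
  for (first in 0:n) {
    rest <- .compositions_of(n - first, k - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  out
}

oracle_envelope <- function(counts) {
  per_el <- list()
  for (el in names(counts)) {
    iso <- oracle_isotopes[[el]]
    n <- counts[[el]]
    parts <- .compositions_of(n, length(iso$dn))
    ab <- apply(parts, 1L, function(p)
      exp(lfactorial(n) - sum(lfactorial(p))) * prod(iso$ab^p))
    dn <- as.integer(parts %*% iso$dn)
    off <- as.numeric(parts %*% iso$off)
    per_el[[el]] <- data.frame(dn = dn, off = off, ab = ab)
  }
  # cross-element cartesian product
  acc <- data.frame(dn = 0L, off = 0, ab = 1)
  for (el in names(per_el)) {
    e <- per_el[[el]]
    acc <- do.call(rbind, lapply(seq_len(nrow(acc)), function(i)
      data.frame(dn = acc$dn[i] + e$dn, off = acc$off[i] + e$off,
                 ab = acc$ab[i] * e$ab)))
  }
  agg_ab <- tapply(acc$ab, acc$dn, sum)
  agg_off <- tapply(acc$ab * acc$off, acc$dn, sum) / agg_ab
  data.frame(dn = as.integer(names(agg_ab)),
             offset = as.numeric(agg_off),
             abundance = as.numeric(agg_ab))
}

# Compare a package envelope with the enumeration oracle over all bins the
# oracle puts real abundance in (the package drops bins below 1e-15).
expect_envelope_matches <- function(counts, tol = 1e-9) {
  oracle <- oracle_envelope(counts)
  k <- max(which(oracle$abundance > 1e-12))
  got <- isotope_envelope(ec(counts), k)
  testthat::expect_gte(nrow(got), k)
  testthat::expect_equal(got$abundance[1:k], oracle$abundance[1:k],
                         tolerance = tol,
                         info = paste(names(counts), counts, collapse = ""))
  testthat::expect_equal(got$offset[1:k], oracle$offset[1:k],
                         tolerance = tol)
}

# A fixed easy template used by several tests: capture site plus a read
# window whose perfect-match 4-mers do not cross-react with other windows.
fixed_template <- function() template_seq("TTAATGACATCGATCGATCGAT", "DNA", "D")
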