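# 4-mer reagent combinatorics: full repertoire, antiparallel complementation
# and complement-paired sublibrary design.

.seq_chars <- function(s) strsplit(s, "")[[1]]

#' Enumerate the full 4-mer repertoire
#'
#' All 256 distinct PNA 4-mer sequences over \{A,C,G,T\}, in deterministic
#' lexicographic order.  The set is closed under antiparallel
#' complementation.
#'
#' @return Character vector of 256 sequences (written C-to-N).
#' @export
enumerate_full_repertoire <- function() {
  g <- expand.grid(.BASES, .BASES, .BASES, .BASES, stringsAsFactors = FALSE)
  sort(apply(g, 1L, paste0, collapse = ""))
}

#' Antiparallel PNA complement
#'
#' Watson-Crick partner of a PNA sequence, returned in the same C-to-N
#' writing convention: position `i` of the output is the complement of
#' position `L - i + 1` of the input (so mask `AxxC` pairs mask `GxxT`).
#' The wildcard letter `x` complements to itself.
#'
#' @param sequence Character vector of sequences (C-to-N).
#' @return Character vector of complements (C-to-N).
#' @export
#' @examples
#' pna_complement("AGTC")
pna_complement <- function(sequence) {
  vapply(sequence, function(s) {
    if (!nzchar(s)) stop("sequence must be non-empty", call. = FALSE)
    ch <- rev(.seq_chars(s))
    bad <- !ch %in% names(.COMP_MAP)
    if (any(bad))
      stop("unknown base(s): ", paste(unique(ch[bad]), collapse = ", "),
           call. = FALSE)
    paste(.COMP_MAP[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Expand a sequence mask
#'
#' @param mask Sequence mask over \{A,C,G,T,x\}; `x` expands over all bases.
#' @return Character vector of all matching sequences, lexicographic order.
#' @export
expand_mask <- function(mask) {
  ch <- .seq_chars(mask)
  bad <- !ch %in% c(.BASES, "x")
  if (any(bad))
    stop("mask letters must be A, C, G, T or x: ", mask, call. = FALSE)
  opts <- lapply(ch, function(c) if (c == "x") .BASES else c)
  g <- do.call(expand.grid, c(rev(opts), stringsAsFactors = FALSE))
  sort(apply(g[, rev(seq_along(opts)), drop = FALSE], 1L, paste0,
             collapse = ""))
}

#' Construct a reagent mix of activated 4-mers
#'
#' @param sequences Character vector of 4-mer sequences (C-to-N).
#' @param conc_uM Concentration per member in uM (recycled); must be > 0.
#' @param n_cap N-terminal cap, one of `"azide"`, `"Fmoc"`, `"acetyl"`.
#' @param activation C-terminal activation state, one of `"sNHS-ester"`,
#'   `"pNP-ester"`, `"free-acid"`, `"hydrolyzed"`.
#' @return A `reagent_mix` data frame with columns `sequence`, `n_cap`,
#'   `activation`, `conc_uM` and attribute `total_uM`.
#' @export
reagent_mix <- function(sequences, conc_uM = 3,
                        n_cap = c("azide", "Fmoc", "acetyl"),
                        activation = c("sNHS-ester", "pNP-ester",
                                       "free-acid", "hydrolyzed")) {
  n_cap <- match.arg(n_cap)
  activation <- match.arg(activation)
  if (any(nchar(sequences) != 4L))
    stop("4-mer sequences must have length exactly 4", call. = FALSE)
  if (any(conc_uM <= 0))
    stop("concentrations must be > 0", call. = FALSE)
  if (anyDuplicated(sequences))
    stop("duplicate 4-mers in mix: ",
         paste(unique(sequences[duplicated(sequences)]), collapse = ", "),
         call. = FALSE)
  invisible(pna_complement(sequences))  # validates the alphabet
  out <- data.frame(sequence = sequences, n_cap = n_cap,
                    activation = activation,
                    conc_uM = rep_len(conc_uM, length(sequences)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("reagent_mix", "data.frame"),
            total_uM = sum(out$conc_uM))
}

#' Total concentration of a reagent mix
#' @param mix A [reagent_mix()].
#' @return Total concentration in uM.
#' @export
mix_total_uM <- function(mix) sum(mix$conc_uM)

#' The full 256-member 4-mer library as a mix
#'
#' @param conc_uM Concentration per member in uM.
#' @inheritParams reagent_mix
#' @return A [reagent_mix()] of all 256 4-mers.
#' @export
full_library_mix <- function(conc_uM = 2, n_cap = "azide",
                             activation = "sNHS-ester") {
  reagent_mix(enumerate_full_repertoire(), conc_uM = conc_uM,
              n_cap = n_cap, activation = activation)
}

#' Build a complement-paired sublibrary from masks
#'
#' Expands wildcard masks over all bases and checks that the resulting set
#' is closed under [pna_complement()] (every member's antiparallel
#' complement is also a member), as required for the complementary-match
#' sequestration effect to operate on every possible mismatch partner.
#' Non-closed designs are rejected with the list of unpaired members.
#'
#' @param masks Character vector of masks over \{A,C,G,T,x\},
#'   e.g. `c("AxxC", "GxxT", "CxxA", "TxxG")`.
#' @param conc_uM Concentration per member in uM.
#' @inheritParams reagent_mix
#' @return A [reagent_mix()].
#' @export
#' @examples
#' m <- build_paired_sublibrary(c("AxxC", "GxxT", "CxxA", "TxxG"))
#' nrow(m)            # 64
#' mix_total_uM(m)    # 128
build_paired_sublibrary <- function(masks, conc_uM = 2, n_cap = "azide",
                                    activation = "sNHS-ester") {
  members <- unlist(lapply(masks, expand_mask), use.names = FALSE)
  if (anyDuplicated(members))
    stop("masks expand to duplicate members: ",
         paste(unique(members[duplicated(members)]), collapse = ", "),
         call. = FALSE)
  unpaired <- setdiff(pna_complement(members), members)
  if (length(unpaired) > 0L)
    stop("sublibrary design is not closed under complementation; ",
         "missing partner(s): ", paste(sort(unpaired), collapse = ", "),
         call. = FALSE)
  reagent_mix(sort(members), conc_uM = conc_uM, n_cap = n_cap,
              activation = activation)
}

#' Write / read a reagent mix as TSV
#'
#' Columns: `sequence`, `n_cap`, `activation`, `conc_uM`; lines starting
#' with `#` are comments.
#'
#' @param mix A [reagent_mix()].
#' @param path Destination / source file path.
#' @return `read_mix` returns a [reagent_mix()]; `write_mix` returns the
#'   path invisibly.
#' @export
write_mix <- function(mix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pnaladder reagent mix v1",
               sprintf("# members=%d total_uM=%g", nrow(mix),
                       mix_total_uM(mix)),
               "sequence\tn_cap\tactivation\tconc_uM"), con)
  writeLines(sprintf("%s\t%s\t%s\t%g", mix$sequence, mix$n_cap,
                     mix$activation, mix$conc_uM), con)
  invisible(path)
}

#' @rdname write_mix
#' @export
read_mix <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  df <- utils::read.delim(text = paste(lines[keep], collapse = "\n"),
                          stringsAsFactors = FALSE)
  need <- c("sequence", "n_cap", "activation", "conc_uM")
  if (!all(need %in% names(df)))
    stop("mix file missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  mix <- reagent_mix(df$sequence, conc_uM = df$conc_uM,
                     n_cap = df$n_cap[1], activation = df$activation[1])
  mix
}
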