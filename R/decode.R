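# The sequencer: reduce a centroided peak list to neutral monoisotopic
# masses, anchor the four primers, and call bases from the single-residue
# mass increments of the offset ladder.

.C13_SPACING <- 1.00335484
.OX_DELTA <- 15.9949146221   # one O: also exactly the G - A residue delta
.AZIDE_DELTA <- 25.9904979   # azide cap minus free amine (N2 - H2)

#' Decoder configuration
#'
#' @param primers The [design_primer_set()] whose declared masses anchor the
#'   ladder.
#' @param tolerance Mass-matching tolerance in Da.  Must be positive and
#'   below half the minimum residue-mass gap (about 9.01 / 2 Da), so that
#'   single-residue increments stay mutually distinguishable; asserted at
#'   construction.
#' @param ppm Alternative tolerance in ppm (mutually exclusive with
#'   `tolerance`); converted at the primer mass scale.
#' @param max_cycles Expected number of extension cycles (read length is at
#'   most `4 * max_cycles`).
#' @param final_cap `"azide"` if the last cycle's products are unreduced
#'   (the standard workflow), `"amine"` if a post-run reduction was done.
#' @param residue_table Residue composition table (default
#'   [pna_residues()]).
#' @return A `decoder_config` list with precomputed residue masses and the
#'   declared masses of the four primer anchors.
#' @export
decoder_config <- function(primers, tolerance = 0.25, ppm = NULL,
                           max_cycles = 2L,
                           final_cap = c("azide", "amine"),
                           residue_table = pna_residues()) {
  stopifnot(inherits(primers, "primer_set"))
  final_cap <- match.arg(final_cap)
  res_m <- residue_masses(residue_table)[c("A", "C", "G", "T")]
  primer_masses <- vapply(names(primers$sequences), function(ln)
    monoisotopic_mass(species_composition(ln, "", "amine", primers)),
    numeric(1))
  if (!is.null(ppm)) {
    if (!missing(tolerance))
      stop("give either tolerance (Da) or ppm, not both", call. = FALSE)
    tolerance <- max(primer_masses) * ppm * 1e-6
  }
  gaps <- abs(diff(sort(res_m)))
  if (tolerance <= 0 || tolerance >= min(gaps) / 2)
    stop(sprintf(
      "tolerance must be in (0, %.3f) Da to keep residue increments distinguishable",
      min(gaps) / 2), call. = FALSE)
  structure(list(primers = primers, tolerance = tolerance,
                 max_cycles = as.integer(max_cycles),
                 final_cap = final_cap,
                 residue_masses = res_m,
                 primer_masses = primer_masses),
            class = "decoder_config")
}

#' Collapse a peak list to neutral monoisotopic masses
#'
#' Groups isotope clusters by the ~1.003 Da spacing and keeps the
#' monoisotopic member (the lightest, not the most intense); folds M+Na and
#' M+K satellites (+21.9819 / +37.9559 from M+H) into their parent;
#' converts to neutral mass by subtracting the proton mass.  Peaks sitting
#' +15.9949 above another peak are retained but annotated as possible
#' oxidation satellites (needed to disambiguate G from A plus oxidation).
#' Nothing is discarded as unassignable: orphan peaks pass through.
#'
#' @param peaks A [peak_list()] (sorted m/z).
#' @param cfg A [decoder_config()].
#' @return `data.frame` with columns `mass` (neutral Da), `intensity`
#'   (cluster plus satellite aggregate) and `ox_annotated` (logical).
#' @export
collapse_to_neutral <- function(peaks, cfg) {
  stopifnot(inherits(cfg, "decoder_config"))
  n <- nrow(peaks)
  if (n == 0L)
    return(data.frame(mass = numeric(0), intensity = numeric(0),
                      ox_annotated = logical(0)))
  mz <- peaks$mz; int <- peaks$intensity
  # greedy envelope extraction: seed each cluster at the most intense
  # unassigned peak and claim members one 13C spacing at a time (nearest
  # match within a few mDa).  Walking out from a seed, rather than chaining
  # adjacent gaps, keeps interleaved envelopes of distinct species apart.
  step_tol <- 0.008
  assigned <- rep(FALSE, n)
  mono <- numeric(0); tot <- numeric(0)
  for (s in order(int, decreasing = TRUE)) {
    if (assigned[s]) next
    members <- s
    assigned[s] <- TRUE
    for (dir in c(1, -1)) {
      cur <- mz[s]
      repeat {
        target <- cur + dir * .C13_SPACING
        j <- which(!assigned & abs(mz - target) <= step_tol)
        if (length(j) == 0L) break
        j <- j[which.min(abs(mz[j] - target))]
        members <- c(members, j)
        assigned[j] <- TRUE
        cur <- mz[j]
      }
    }
    mono <- c(mono, min(mz[members]))
    tot <- c(tot, sum(int[members]))
  }
  ord <- order(mono)
  mono <- mono[ord]; tot <- tot[ord]
  # fold Na/K adduct satellites into their M+H parent.  The adduct offsets
  # are exact chemical constants, so the match window is narrow, and a true
  # satellite is always fainter than its parent (minor adduct fractions):
  # both guards keep a genuine ladder rung from being folded into an
  # unrelated peak that happens to sit one adduct offset below it.
  tol <- cfg$tolerance
  sat_tol <- min(tol, 0.02)
  na_off <- .ATOMIC_MASSES[["Na"]] - .ATOMIC_MASSES[["H"]]
  k_off <- .ATOMIC_MASSES[["K"]] - .ATOMIC_MASSES[["H"]]
  keep <- rep(TRUE, length(mono))
  for (i in seq_along(mono)) {
    for (off in c(na_off, k_off)) {
      j <- which(abs(mono - (mono[i] - off)) <= sat_tol & keep &
                   tot > tot[i] / 0.6)
      j <- setdiff(j, i)
      if (length(j) > 0L) {
        j <- j[which.min(abs(mono[j] - (mono[i] - off)))]
        tot[j] <- tot[j] + tot[i]
        keep[i] <- FALSE
        break
      }
    }
  }
  mono <- mono[keep]; tot <- tot[keep]
  mass <- mono - .PROTON_MASS
  ox <- vapply(seq_along(mass), function(i)
    any(abs(mass - (mass[i] - .OX_DELTA)) <= tol & seq_along(mass) != i),
    logical(1))
  out <- data.frame(mass = mass, intensity = tot, ox_annotated = ox)
  rownames(out) <- NULL
  out[order(out$mass), , drop = FALSE]
}

#' Anchor the four primer masses in a neutral-mass list
#'
#' Each primer (P, P-1, P-2, P-3) is matched to its declared monoisotopic
#' mass within tolerance.  Decoding needs at least two anchors; fewer is a
#' hard failure (`pnaladder_no_anchor` condition) since the ladder then has
#' no origin.  A constant calibration offset beyond tolerance therefore
#' stops decoding (recalibration is out of scope).
#'
#' @param neutrals Output of [collapse_to_neutral()].
#' @param cfg A [decoder_config()].
#' @return Named numeric vector of observed anchor masses (NA where a
#'   primer was not found).
#' @export
anchor_primers <- function(neutrals, cfg) {
  obs <- vapply(cfg$primer_masses, function(m) {
    i <- which(abs(neutrals$mass - m) <= cfg$tolerance)
    if (length(i) == 0L) return(NA_real_)
    neutrals$mass[i[which.max(neutrals$intensity[i])]]
  }, numeric(1))
  if (sum(!is.na(obs)) < 2L)
    stop(structure(class = c("pnaladder_no_anchor", "error", "condition"),
                   list(message = paste0(
                     "no ladder origin: fewer than 2 primer anchors found (",
                     sum(!is.na(obs)), "/4)"), call = NULL)))
  obs
}

# lineage of the k-th ladder rung above the full primer
.rung_lineage <- function(k) c("P-3", "P-2", "P-1", "P")[(k - 1L) %% 4L + 1L]

#' Call bases from the mass-increment ladder
#'
#' Starting from the full primer's mass, the decoder walks the sorted
#' neutral masses: each step looks for a peak one residue mass above the
#' current rung (with, at one point in the chain, the extra azide-cap delta
#' marking the transition from reduced intermediate products to the
#' final-cycle azide-capped products).  Among matching candidates the most
#' intense peak wins, which also resolves the G versus A+oxidation
#' confound: a genuine G rung outweighs the faint +16 satellite of an A
#' rung, and vice versa.  A gap matching no residue truncates the read; if
#' a two-residue gap to a real peak is detected, the position is flagged
#' `missing-rung`.  The decoder never guesses.
#'
#' @param neutrals Output of [collapse_to_neutral()].
#' @param anchors Output of [anchor_primers()].
#' @param cfg A [decoder_config()].
#' @return A `sequence_read` object; see [decode_spectrum()].
#' @export
call_ladder <- function(neutrals, anchors, cfg) {
  tol <- cfg$tolerance
  res_m <- cfg$residue_masses
  cur <- if (!is.na(anchors[["P"]])) anchors[["P"]] else
    cfg$primer_masses[["P"]]
  cap_state <- "reduced"
  used <- rep(FALSE, nrow(neutrals))
  for (ln in names(cfg$primer_masses)) {
    i <- which(abs(neutrals$mass - cfg$primer_masses[[ln]]) <= tol)
    used[i] <- TRUE
  }
  calls <- list()
  flags_all <- character(0)
  for (pos in seq_len(4L * cfg$max_cycles)) {
    cand <- data.frame(base = character(0), target = numeric(0),
                       idx = integer(0), transition = logical(0))
    for (b in names(res_m)) {
      targets <- cur + res_m[[b]]
      trans <- FALSE
      if (cap_state == "reduced" && cfg$final_cap == "azide") {
        targets <- c(targets, cur + res_m[[b]] + .AZIDE_DELTA)
        trans <- c(FALSE, TRUE)
      }
      for (t in seq_along(targets)) {
        i <- which(abs(neutrals$mass - targets[t]) <= tol)
        if (length(i) == 0L) next
        i <- i[which.max(neutrals$intensity[i])]
        cand <- rbind(cand, data.frame(base = b, target = targets[t],
                                       idx = i, transition = trans[t]))
      }
    }
    if (nrow(cand) == 0L) {
      # two-residue lookahead: is the next-but-one rung present?
      two <- outer(res_m, res_m, "+")
      steps <- unique(as.numeric(two))
      if (cap_state == "reduced" && cfg$final_cap == "azide")
        steps <- c(steps, steps + .AZIDE_DELTA)
      hit <- any(vapply(steps, function(s)
        any(abs(neutrals$mass - (cur + s)) <= tol), logical(1)))
      if (hit) flags_all <- c(flags_all, sprintf("missing-rung@%d", pos))
      break
    }
    pick <- cand[which.max(neutrals$intensity[cand$idx]), ]
    flags <- character(0)
    if (pick$base == "G") {
      # the G increment equals A + O exactly; if the peak is annotated as a
      # possible oxidation satellite and an A rung of comparable intensity
      # exists, the assignment is ambiguous
      a_row <- cand[cand$base == "A" & cand$transition == pick$transition, ]
      if (nrow(a_row) > 0L && neutrals$ox_annotated[pick$idx]) {
        r <- neutrals$intensity[pick$idx] /
          max(neutrals$intensity[a_row$idx])
        # a G rung normally outweighs the A interpretation by the full
        # mismatch margin; a win under 1.5x is a marginal decision
        if (r < 1.5) flags <- c(flags, "oxidation-confounded")
      }
    }
    obs_mass <- neutrals$mass[pick$idx]
    if (length(calls) > 0L &&
        neutrals$intensity[pick$idx] <
          0.01 * neutrals$intensity[calls[[1]]$idx])
      flags <- c(flags, "low-intensity")
    calls[[pos]] <- data.frame(
      position = pos, base = pick$base,
      observed_increment = obs_mass - cur,
      increment_error_mDa = 1000 * (obs_mass - pick$target),
      lineage = .rung_lineage(pos),
      flags = paste(flags, collapse = ";"),
      idx = pick$idx,
      stringsAsFactors = FALSE)
    flags_all <- c(flags_all, flags)
    used[pick$idx] <- TRUE
    if (pick$transition) cap_state <- "capped"
    cur <- obs_mass
  }
  calls_df <- if (length(calls) > 0L) do.call(rbind, calls) else
    data.frame(position = integer(0), base = character(0),
               observed_increment = numeric(0),
               increment_error_mDa = numeric(0), lineage = character(0),
               flags = character(0), idx = integer(0))
  min_anchor <- min(cfg$primer_masses)
  orphan <- !used & neutrals$mass > min_anchor - cfg$tolerance
  orphans <- neutrals[orphan, c("mass", "intensity"), drop = FALSE]
  rownames(orphans) <- NULL
  calls_df$idx <- NULL
  structure(list(calls = calls_df,
                 anchors = anchors,
                 n_anchors = sum(!is.na(anchors)),
                 orphans = orphans,
                 flags = flags_all,
                 chirality = switch(cfg$primers$chirality_preference,
                                    "binds-D" = "D", "binds-L" = "L"),
                 sequence = paste(calls_df$base, collapse = "")),
            class = "sequence_read")
}

#' Decode a spectrum into a sequence read
#'
#' Composition of [collapse_to_neutral()], [anchor_primers()] and
#' [call_ladder()].  The read carries per-call evidence (observed increment
#' and error in mDa, supporting primer-offset lineage, flags), the anchor
#' report, the minority orphan peaks that supported no call, and the
#' template chirality implied by which primer set anchored.  A call is
#' never emitted without a supporting mass increment; on a primer-only
#' spectrum (failed capture, wrong chirality) the read is empty.
#'
#' @param peaks A [peak_list()] or path readable by [read_peaklist()].
#' @param cfg A [decoder_config()].
#' @return A `sequence_read` object.
#' @export
decode_spectrum <- function(peaks, cfg) {
  if (is.character(peaks)) peaks <- read_peaklist(peaks)
  neutrals <- collapse_to_neutral(peaks, cfg)
  anchors <- anchor_primers(neutrals, cfg)
  call_ladder(neutrals, anchors, cfg)
}

#' @export
print.sequence_read <- function(x, ...) {
  cat("<sequence_read>\n")
  cat(sprintf("  anchors found : %d/4\n", x$n_anchors))
  cat(sprintf("  chirality tag : %s (from primer set)\n", x$chirality))
  if (nrow(x$calls) == 0L) {
    cat("  read          : (empty - no extension products)\n")
  } else {
    cat(sprintf("  read (C->N)   : %s  (%d calls)\n", x$sequence,
                nrow(x$calls)))
    cat("  per-call evidence:\n")
    for (i in seq_len(nrow(x$calls))) {
      r <- x$calls[i, ]
      cat(sprintf("    %2d  %s  +%9.4f Da  (%+6.1f mDa, %s)%s\n",
                  r$position, r$base, r$observed_increment,
                  r$increment_error_mDa, r$lineage,
                  if (nzchar(r$flags)) paste0("  [", r$flags, "]") else ""))
    }
  }
  if (length(x$flags) > 0L)
    cat("  flags         :", paste(x$flags, collapse = ", "), "\n")
  cat(sprintf("  orphan peaks  : %d\n", nrow(x$orphans)))
  invisible(x)
}

#' Expected base calls for a template
#'
#' The PNA residues that perfect-match extension incorporates, in order of
#' incorporation (complements of the template bases immediately 5' of the
#' primer footprint, walked toward the template 5' end).
#'
#' @param template A [template_seq()].
#' @param primer_length Primer length used.
#' @param n_calls Number of calls expected (default 8, two cycles).
#' @return Character string of expected calls.
#' @export
expected_calls <- function(template, primer_length = 14L, n_calls = 8L) {
  L <- nchar(template$sequence)
  p <- L - primer_length + 1L
  idx <- p - seq_len(n_calls)
  idx <- idx[idx >= 1L]
  ch <- .seq_chars(template$sequence)[idx]
  paste(.COMP_MAP[ch], collapse = "")
}

#' Per-base accuracy of a read against its template
#'
#' @param read A `sequence_read`.
#' @param template The [template_seq()] that templated the reaction.
#' @param primer_length Primer length used.
#' @param n_calls Expected read length.
#' @return Fraction of expected positions called correctly (an empty read
#'   scores 0).
#' @export
read_accuracy <- function(read, template, primer_length = 14L,
                          n_calls = 8L) {
  expect <- expected_calls(template, primer_length, n_calls)
  got <- read$sequence
  n <- nchar(expect)
  if (n == 0L) return(NA_real_)
  k <- min(nchar(got), n)
  if (k == 0L) return(0)
  hits <- sum(.seq_chars(got)[seq_len(k)] == .seq_chars(expect)[seq_len(k)])
  hits / n
}
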