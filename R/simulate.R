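# Kinetic simulator of cyclic, enzyme-free primer extension with reversible
# azide termination.  Expectation mode propagates population fractions
# (MALDI intensities are population averages); a seeded stochastic mode
# samples individual molecules for cross-checking.

#' Define a template to be sequenced
#'
#' @param sequence Base string over \{A,C,G,T\}.  DNA/LNA templates are
#'   written 5'-to-3', PNA templates N-to-C; in either convention the primer
#'   capture site is the trailing end of the string and extension reads
#'   toward the leading end.
#' @param polymer One of `"DNA"`, `"LNA"`, `"PNA"`.
#' @param chirality `"D"`, `"L"` or `"achiral"`.  PNA templates are achiral;
#'   DNA and LNA must be D or L.  Defaults to `"D"` for DNA/LNA and
#'   `"achiral"` for PNA.
#' @return A `pna_template` object.
#' @export
#' @examples
#' template_seq("ACGTTGCAATCCGGATTGCACT", "DNA", "D")
template_seq <- function(sequence, polymer = c("DNA", "LNA", "PNA"),
                         chirality = NULL) {
  polymer <- match.arg(polymer)
  ch <- .seq_chars(sequence)
  if (!all(ch %in% .BASES))
    stop("template bases must be A, C, G or T", call. = FALSE)
  if (is.null(chirality))
    chirality <- if (polymer == "PNA") "achiral" else "D"
  chirality <- match.arg(chirality, c("D", "L", "achiral"))
  if (polymer == "PNA" && chirality != "achiral")
    stop("PNA templates are achiral", call. = FALSE)
  if (polymer != "PNA" && chirality == "achiral")
    stop(polymer, " templates must have chirality D or L", call. = FALSE)
  structure(list(sequence = sequence, polymer = polymer,
                 chirality = chirality),
            class = "pna_template")
}

#' Design the four-primer deletion set for a template
#'
#' The full primer P is the antiparallel PNA complement of the template
#' capture site (the trailing `primer_length` bases); P-1, P-2 and P-3
#' remove one, two and three residues from its N-terminus.  Extending the
#' four primers in parallel converts the 4-residue additions of each cycle
#' into a ladder of single-residue mass increments.
#'
#' @param template A [template_seq()].
#' @param primer_length Primer length in residues (default 14; the paper's
#'   capture duplex regime where binding is effectively binary).
#' @param chirality_preference `"binds-D"` or `"binds-L"`: which template
#'   chirality the (chirally pure) primer hybridizes to.  Defaults to the
#'   template's own chirality (`"binds-D"` for achiral templates).
#' @param dead_fraction Fraction in \[0, 1) of each primer that never
#'   extends once loaded on the bead; these molecules provide the anchor
#'   peaks used by the decoder.
#' @param loading Relative amount loaded per primer.
#' @param c_terminus C-terminal state of the primers (default
#'   `"linker-biotin"` for streptavidin capture).
#' @param linker_composition Composition of the C-terminal linker.
#' @return A `primer_set` object with the four primer sequences (written
#'   C-to-N), termini configuration and loading parameters.
#' @export
design_primer_set <- function(template, primer_length = 14L,
                              chirality_preference = NULL,
                              dead_fraction = 0.3, loading = 1,
                              c_terminus = "linker-biotin",
                              linker_composition = default_biotin_linker()) {
  stopifnot(inherits(template, "pna_template"))
  L <- nchar(template$sequence)
  if (L < primer_length)
    stop("template shorter than the primer", call. = FALSE)
  if (dead_fraction < 0 || dead_fraction >= 1)
    stop("dead_fraction must be in [0, 1)", call. = FALSE)
  if (is.null(chirality_preference)) {
    chirality_preference <- switch(template$chirality,
                                   D = "binds-D", L = "binds-L",
                                   achiral = "binds-D")
  }
  chirality_preference <- match.arg(chirality_preference,
                                    c("binds-D", "binds-L"))
  capture <- substr(template$sequence, L - primer_length + 1L, L)
  P <- pna_complement(capture)
  seqs <- vapply(0:3, function(k) substr(P, 1L, primer_length - k),
                 character(1))
  names(seqs) <- c("P", "P-1", "P-2", "P-3")
  termini <- termini_state("free-amine", c_terminus,
                           linker_composition = linker_composition)
  structure(list(sequences = seqs, primer_length = primer_length,
                 chirality_preference = chirality_preference,
                 dead_fraction = dead_fraction, loading = loading,
                 termini = termini),
            class = "primer_set")
}

#' Kinetics configuration for the primer-extension simulator
#'
#' Defaults are the package's calibration of the templated-ligation
#' chemistry: extension half-life about 2 min at the 3 uM reference
#' concentration, ester hydrolysis half-life over 250 min, 4 min reaction
#' time per cycle, a 1:1 perfect-match to terminal-mismatch incorporation
#' ratio that moves to 4:1 when the mismatch 4-mer's complement is present
#' (sequestration), a 6-fold extension penalty on strands that terminated
#' the previous cycle with a terminal mismatch, and a helper effect (an
#' adjacent downstream 4-mer in the mix) that doubles the rate and the
#' mismatch discrimination.
#'
#' @param t_half_extension Extension half-life in minutes at reference
#'   conditions.
#' @param t_half_hydrolysis Activated-ester hydrolysis half-life in minutes
#'   (competing first-order channel on the reagent pool).
#' @param t_half_pnp Extension half-life preset for pNP-ester reagents.
#' @param reaction_time Reaction time per cycle in minutes.
#' @param ref_conc_uM Reference 4-mer concentration in uM at which
#'   `t_half_extension` applies.
#' @param K_D,k_off 4-mer hybridization constants (uM, s^-1); informational,
#'   retained for a future explicit-equilibrium mode.
#' @param terminal_mm_weight Relative incorporation weight of a 4-mer with a
#'   single terminal mismatch (either ligation-distal N-terminal position or
#'   C-terminal position of the 4-mer as written).
#' @param internal_mm_weight Weight of a single internal mismatch.
#' @param multi_mm_weight Weight of two or more mismatches.
#' @param cm_sequestration_factor Multiplier applied to a mismatch weight
#'   when that 4-mer's complement is present in the mix.
#' @param post_mm_extension_penalty Factor by which the extension conversion
#'   of a strand whose last addition carried a terminal mismatch is reduced.
#' @param helper_factor Rate multiplier (and mismatch-weight divisor) when
#'   the downstream adjacent perfect-match 4-mer is present in the mix.
#' @param nonadjacent_weight Weight of 4-mers hybridizing with a 1-2 nt gap
#'   from the primer terminus (adjacent hybridization strongly favored).
#' @param reduction_efficiency Fraction of azide caps reduced to free amines
#'   per deprotection step.
#' @param rng_seed Optional seed for stochastic mode.
#' @return A `kinetics_config` list.
#' @export
kinetics_config <- function(t_half_extension = 2,
                            t_half_hydrolysis = 300,
                            t_half_pnp = 180,
                            reaction_time = 4,
                            ref_conc_uM = 3,
                            K_D = 8, k_off = 1,
                            terminal_mm_weight = 1.0,
                            internal_mm_weight = 0.01,
                            multi_mm_weight = 0,
                            cm_sequestration_factor = 0.25,
                            post_mm_extension_penalty = 6,
                            helper_factor = 2,
                            nonadjacent_weight = 0,
                            reduction_efficiency = 1.0,
                            rng_seed = NULL) {
  cfg <- list(t_half_extension = t_half_extension,
              t_half_hydrolysis = t_half_hydrolysis,
              t_half_pnp = t_half_pnp,
              reaction_time = reaction_time,
              ref_conc_uM = ref_conc_uM,
              K_D = K_D, k_off = k_off,
              terminal_mm_weight = terminal_mm_weight,
              internal_mm_weight = internal_mm_weight,
              multi_mm_weight = multi_mm_weight,
              cm_sequestration_factor = cm_sequestration_factor,
              post_mm_extension_penalty = post_mm_extension_penalty,
              helper_factor = helper_factor,
              nonadjacent_weight = nonadjacent_weight,
              reduction_efficiency = reduction_efficiency,
              rng_seed = rng_seed)
  stopifnot(t_half_extension > 0, t_half_hydrolysis > 0, reaction_time >= 0,
            terminal_mm_weight >= 0, internal_mm_weight >= 0,
            multi_mm_weight >= 0, cm_sequestration_factor >= 0,
            post_mm_extension_penalty >= 1, helper_factor > 0,
            nonadjacent_weight >= 0,
            reduction_efficiency >= 0, reduction_efficiency <= 1)
  structure(cfg, class = "kinetics_config")
}

#' Can a primer set capture a template?
#'
#' Capture succeeds iff the template is achiral (PNA) or the primer set's
#' chirality preference matches the template chirality, and the full primer
#' is the antiparallel complement of the template capture site.  A failed
#' capture is a result, not an error: downstream simulation then yields the
#' unreacted primers only.
#'
#' @param template A [template_seq()].
#' @param primers A [design_primer_set()].
#' @return List with `captured` (logical) and `reason`.
#' @export
check_capture <- function(template, primers) {
  stopifnot(inherits(template, "pna_template"),
            inherits(primers, "primer_set"))
  want <- switch(primers$chirality_preference, "binds-D" = "D",
                 "binds-L" = "L")
  if (template$chirality != "achiral" && template$chirality != want)
    return(list(captured = FALSE,
                reason = sprintf("primer chirality (%s) does not match %s template",
                                 primers$chirality_preference,
                                 template$chirality)))
  L <- nchar(template$sequence)
  pl <- primers$primer_length
  if (L < pl)
    return(list(captured = FALSE, reason = "template shorter than primer"))
  capture <- substr(template$sequence, L - pl + 1L, L)
  if (!identical(pna_complement(capture), unname(primers$sequences[["P"]])))
    return(list(captured = FALSE,
                reason = "primer not complementary to the template capture site"))
  list(captured = TRUE, reason = "ok")
}

#' Fraction of primer extended after a templated reaction
#'
#' First-order extension, `1 - 2^(-t / t_half)`, with hydrolysis of the
#' activated-ester pool as a competing parallel first-order channel: the
#' effective extension rate decays with the ester pool, giving
#' `1 - exp(-(k_e / k_h) (1 - exp(-k_h t)))`.  With no hydrolysis
#' (`t_half_hydrolysis = Inf`) this reduces to the plain first-order form.
#'
#' @param t Reaction time in minutes (>= 0).
#' @param t_half Extension half-life in minutes (> 0).
#' @param t_half_hydrolysis Ester hydrolysis half-life in minutes.
#' @return Fraction extended in \[0, 1\].
#' @export
#' @examples
#' extension_conversion(4, 2)        # 0.75
extension_conversion <- function(t, t_half, t_half_hydrolysis = Inf) {
  if (any(t < 0)) stop("reaction time must be >= 0", call. = FALSE)
  if (t_half <= 0) stop("t_half must be > 0", call. = FALSE)
  ke <- log(2) / t_half
  if (!is.finite(t_half_hydrolysis)) return(1 - exp(-ke * t))
  kh <- log(2) / t_half_hydrolysis
  1 - exp(-(ke / kh) * (1 - exp(-kh * t)))
}

# Classify a 4-mer against the perfect match for a template site.
# Positions are in the C-to-N writing of the 4-mer; position 4 (N-terminal,
# ligation-distal) and position 1 (C-terminal) count as terminal.
.classify_fourmer <- function(fourmer, pm) {
  mm <- which(.seq_chars(fourmer) != .seq_chars(pm))
  if (length(mm) == 0L) return("PM")
  if (length(mm) > 1L) return("multi")
  if (mm %in% c(1L, 4L)) "terminal" else "internal"
}

#' Incorporation weights of mix members competing for a template site
#'
#' The perfect match (the antiparallel complement of the 4-nt window) gets
#' weight 1; a single terminal mismatch gets `terminal_mm_weight`, scaled by
#' `cm_sequestration_factor` if that 4-mer's complement is present in the
#' mix (sequestration into solution-phase 4-mer:4-mer duplexes); a single
#' internal mismatch gets `internal_mm_weight`; two or more mismatches get
#' `multi_mm_weight`.  When a helper (the downstream adjacent perfect-match
#' 4-mer) is present, mismatch weights are divided by `helper_factor`.
#' Weights are proportional to concentration (relative to `ref_conc_uM`)
#' and, for pNP esters, reduced by the slower pNP rate preset; hydrolyzed or
#' unactivated members get weight 0.  Incorporation probabilities are
#' proportional to these weights.
#'
#' @param window Template 4-nt window, written 5'-to-3' (the positions the
#'   incoming 4-mer pairs with).
#' @param mix A [reagent_mix()].
#' @param cfg A [kinetics_config()].
#' @param helper_present Is the downstream adjacent perfect-match 4-mer in
#'   the mix?
#' @return Named numeric vector of weights (one per mix member) with
#'   attribute `class_of` giving the mismatch class per member.
#' @export
competition_weights <- function(window, mix, cfg = kinetics_config(),
                                helper_present = FALSE) {
  stopifnot(nchar(window) == 4L, nrow(mix) >= 1L)
  pm <- pna_complement(window)
  cls <- vapply(mix$sequence, .classify_fourmer, character(1), pm = pm)
  base_w <- c(PM = 1, terminal = cfg$terminal_mm_weight,
              internal = cfg$internal_mm_weight,
              multi = cfg$multi_mm_weight)[cls]
  has_cm <- mix$sequence %in% pna_complement(mix$sequence)
  seq_f <- ifelse(cls != "PM" & has_cm, cfg$cm_sequestration_factor, 1)
  help_f <- if (helper_present)
    ifelse(cls == "PM", 1, 1 / cfg$helper_factor) else 1
  act_f <- vapply(mix$activation, function(a) switch(a,
      "sNHS-ester" = 1,
      "pNP-ester"  = cfg$t_half_extension / cfg$t_half_pnp,
      0), numeric(1))
  w <- base_w * seq_f * help_f * act_f * mix$conc_uM / cfg$ref_conc_uM
  names(w) <- mix$sequence
  attr(w, "class_of") <- stats::setNames(unname(cls), mix$sequence)
  w
}

# Template index of the primer-P N-terminal pairing position.
.p_anchor <- function(template, primers) {
  nchar(template$sequence) - primers$primer_length + 1L
}

# Fresh simulation state: one dead and one live row per primer.
.initial_state <- function(primers, stochastic = FALSE, n_molecules = NULL) {
  k <- 0:3
  if (stochastic) {
    dead_n <- stats::rbinom(4L, n_molecules, primers$dead_fraction)
    ab_dead <- as.numeric(dead_n)
    ab_live <- as.numeric(n_molecules - dead_n)
  } else {
    ab_dead <- rep(primers$loading * primers$dead_fraction, 4L)
    ab_live <- rep(primers$loading * (1 - primers$dead_fraction), 4L)
  }
  data.frame(
    lineage = rep(names(primers$sequences), 2L),
    offset = rep(k, 2L),
    added = "",
    cap = "amine",
    dead = rep(c(TRUE, FALSE), each = 4L),
    post_mm = FALSE,
    abundance = c(ab_dead, ab_live),
    stringsAsFactors = FALSE)
}

#' Run one cycle of primer extension
#'
#' Each extendable species (free-amine N-terminus, not dead, template
#' remaining) gains at most one 4-mer; the azide cap on the incoming 4-mer
#' blocks further addition within the cycle.  The converted fraction is
#' distributed over competing mix members in proportion to
#' [competition_weights()]; strands whose previous addition carried a
#' terminal mismatch extend with their conversion reduced by
#' `post_mm_extension_penalty`.
#'
#' @param state Simulation state data frame (see [run_protocol()]).
#' @param template A [template_seq()].
#' @param primers A [design_primer_set()].
#' @param mix A [reagent_mix()].
#' @param cfg A [kinetics_config()].
#' @param stochastic Sample molecule counts instead of propagating expected
#'   fractions.
#' @return Updated state data frame.
#' @export
run_cycle <- function(state, template, primers, mix,
                      cfg = kinetics_config(), stochastic = FALSE) {
  if (all(mix$activation == "hydrolyzed")) {
    warning("reagent mix fully hydrolyzed; no extension", call. = FALSE)
    return(state)
  }
  if (cfg$reaction_time == 0) return(state)
  p <- .p_anchor(template, primers)
  tseq <- template$sequence
  weight_cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(state))
  for (i in seq_len(nrow(state))) {
    row <- state[i, ]
    q <- p + row$offset - nchar(row$added)
    if (row$cap != "amine" || row$dead || q - 4L < 1L ||
        row$abundance == 0) {
      out[[i]] <- row
      next
    }
    window <- substr(tseq, q - 4L, q - 1L)
    helper <- q - 8L >= 1L &&
      pna_complement(substr(tseq, q - 8L, q - 5L)) %in% mix$sequence
    key <- paste0(window, ":", helper)
    w <- weight_cache[[key]]
    if (is.null(w)) {
      w <- competition_weights(window, mix, cfg, helper_present = helper)
      weight_cache[[key]] <- w
    }
    s <- sum(w)
    if (s <= 0) { out[[i]] <- row; next }
    # saturating-site kinetics: the templated site turns over at the
    # calibrated rate once reagent weight saturates it (min(1, sum w));
    # the calibrated half-life refers to the standard helper-present
    # protocol, so a missing downstream helper slows the rate instead of
    # a present one accelerating it.  Weights only split the converted
    # pool among competing 4-mers.
    rate_scale <- min(1, s) * (if (helper) 1 else 1 / cfg$helper_factor)
    conv <- extension_conversion(cfg$reaction_time,
                                 cfg$t_half_extension / rate_scale,
                                 cfg$t_half_hydrolysis)
    if (row$post_mm) conv <- conv / cfg$post_mm_extension_penalty
    keep <- w > 0
    share <- w[keep] / sum(w[keep])
    cls <- attr(w, "class_of")[keep]
    if (stochastic) {
      n_ext <- stats::rbinom(1L, row$abundance, conv)
      alloc <- if (n_ext > 0)
        as.numeric(stats::rmultinom(1L, n_ext, share)) else numeric(length(share))
      ab_new <- alloc
      ab_rest <- row$abundance - n_ext
    } else {
      ab_new <- row$abundance * conv * share
      ab_rest <- row$abundance * (1 - conv)
    }
    rest <- row
    rest$abundance <- ab_rest
    nz <- ab_new > 0
    if (!any(nz)) { out[[i]] <- rest; next }
    new <- row[rep(1L, sum(nz)), ]
    new$added <- paste0(row$added, names(share)[nz])
    new$cap <- mix$n_cap[match(names(share)[nz], mix$sequence)]
    new$cap <- ifelse(new$cap == "azide", "azide", new$cap)
    new$post_mm <- cls[nz] == "terminal"
    new$abundance <- ab_new[nz]
    out[[i]] <- rbind(rest, new)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[res$abundance > 0, , drop = FALSE]
}

# Azide -> amine reduction applied to the whole bead population.
.reduce_state <- function(state, efficiency) {
  az <- state$cap == "azide"
  if (!any(az) || efficiency == 0) return(state)
  if (efficiency >= 1) {
    state$cap[az] <- "amine"
    return(state)
  }
  red <- state[az, ]
  red$cap <- "amine"
  red$abundance <- red$abundance * efficiency
  state$abundance[az] <- state$abundance[az] * (1 - efficiency)
  rbind(state, red)
}

#' Perfect-match 4-mer mix for a given cycle
#'
#' The four 4-mers that perfectly complement the four lineage windows of a
#' cycle (the mix used in the single-template validation experiments).
#'
#' @inheritParams run_cycle
#' @param cycle Cycle number (1-based).
#' @param conc_uM Concentration per member in uM.
#' @return A [reagent_mix()].
#' @export
pm_mix_for_cycle <- function(template, primers, cycle, conc_uM = 3) {
  p <- .p_anchor(template, primers)
  seqs <- unique(vapply(0:3, function(k) {
    q <- p + k - 4L * (cycle - 1L)
    if (q - 4L < 1L) return(NA_character_)
    pna_complement(substr(template$sequence, q - 4L, q - 1L))
  }, character(1)))
  seqs <- seqs[!is.na(seqs)]
  reagent_mix(seqs, conc_uM = conc_uM)
}

#' Run a full cyclic extension protocol
#'
#' Alternates extension cycles ([run_cycle()]) with azide-to-amine
#' reduction between cycles (reversible termination); the final cycle's
#' products retain their azide caps.  The unreacted dead fraction of every
#' primer is retained throughout and guarantees the anchor peaks the
#' decoder starts from.  If capture fails (wrong chirality or
#' non-complementary primer) the returned state contains the primers only.
#'
#' @inheritParams run_cycle
#' @param mixes A single [reagent_mix()] used for every cycle, or a list of
#'   mixes, one per cycle.
#' @param n_cycles Number of extension cycles (>= 1).
#' @param mode `"expectation"` (deterministic population fractions, the
#'   default) or `"stochastic"` (seeded per-molecule sampling).
#' @param n_molecules Molecules per primer in stochastic mode.
#' @param seed RNG seed for stochastic mode (defaults to `cfg$rng_seed`).
#' @param prune Abundance floor relative to the per-primer loading below
#'   which species are dropped (expectation mode only).
#' @return A `species_abundance` data frame with one row per product
#'   species: `lineage`, `offset` (deletion count), `added` (residues added
#'   C-to-N), `cap` (`"amine"`/`"azide"`), `post_mm`, `abundance`.
#'   Attributes carry the template, primer set, config and capture result.
#' @export
run_protocol <- function(template, primers = NULL, mixes, n_cycles = 2L,
                         cfg = kinetics_config(),
                         mode = c("expectation", "stochastic"),
                         n_molecules = 1e5, seed = NULL,
                         prune = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(n_cycles >= 1L)
  if (is.null(primers)) primers <- design_primer_set(template)
  if (inherits(mixes, "reagent_mix")) mixes <- rep(list(mixes), n_cycles)
  if (length(mixes) != n_cycles)
    stop("need one reagent mix per cycle", call. = FALSE)
  stochastic <- mode == "stochastic"
  if (stochastic) {
    if (is.null(seed)) seed <- cfg$rng_seed
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
  }
  cap <- check_capture(template, primers)
  state <- .initial_state(primers, stochastic,
                          n_molecules = if (stochastic) n_molecules else NULL)
  if (cap$captured) {
    for (cyc in seq_len(n_cycles)) {
      state <- run_cycle(state, template, primers, mixes[[cyc]], cfg,
                         stochastic = stochastic)
      if (cyc < n_cycles)
        state <- .reduce_state(state, cfg$reduction_efficiency)
      if (!stochastic)
        state <- state[state$abundance >= prune * primers$loading, ,
                       drop = FALSE]
    }
  }
  key <- paste(state$lineage, state$added, state$cap, state$post_mm,
               sep = "\r")
  ab <- vapply(split(state$abundance, key), sum, numeric(1))
  first <- state[!duplicated(key), , drop = FALSE]
  first <- first[match(names(ab), key[!duplicated(key)]), , drop = FALSE]
  first$abundance <- as.numeric(ab)
  first$dead <- NULL
  first <- first[order(first$lineage, nchar(first$added), first$added,
                       first$cap), , drop = FALSE]
  rownames(first) <- NULL
  structure(first, class = c("species_abundance", "data.frame"),
            template = template, primer_set = primers, cfg = cfg,
            captured = cap$captured, mode = mode,
            n_molecules = if (stochastic) n_molecules else NULL)
}

#' Neutral composition of a simulated species
#'
#' Primer residues plus added residues, with the N-terminal cap state and
#' the primer-set C-terminus; mass bookkeeping is fully delegated to the
#' composition arithmetic in [compose_oligomer()].
#'
#' @param lineage Primer lineage name (`"P"`, `"P-1"`, `"P-2"`, `"P-3"`).
#' @param added Residues added by extension (C-to-N), possibly `""`.
#' @param cap `"amine"` or `"azide"`.
#' @param primers The [design_primer_set()] the species derives from.
#' @param oxidations Extra oxygen count.
#' @return An [ec()] composition.
#' @export
species_composition <- function(lineage, added, cap, primers,
                                oxidations = 0L) {
  seqs <- paste0(primers$sequences[[lineage]], added)
  termini <- termini_state(
    n_terminus = if (cap == "azide") "azide" else "free-amine",
    c_terminus = primers$termini$c_terminus,
    linker_composition = primers$termini$linker_composition)
  compose_oligomer(seqs, termini, oxidations = oxidations)
}

#' Write / read a species-abundance table as TSV
#'
#' Columns `lineage`, `offset`, `added`, `cap`, `post_mm`, `abundance`; the
#' header comments carry the primer-set definition so the spectrum
#' generator can reconstruct species masses from the file alone.
#'
#' @param species A `species_abundance` from [run_protocol()].
#' @param path Destination / source path.
#' @return `read_species` returns a `species_abundance`; `write_species`
#'   the path, invisibly.
#' @export
write_species <- function(species, path) {
  ps <- attr(species, "primer_set")
  tpl <- attr(species, "template")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# pnaladder species v1",
    sprintf("# primer_P=%s", ps$sequences[["P"]]),
    sprintf("# primer_length=%d", ps$primer_length),
    sprintf("# chirality_preference=%s", ps$chirality_preference),
    sprintf("# dead_fraction=%g", ps$dead_fraction),
    sprintf("# loading=%g", ps$loading),
    sprintf("# c_terminus=%s", ps$termini$c_terminus),
    sprintf("# linker=%s", format(ps$termini$linker_composition %||% ec(NULL))),
    sprintf("# template=%s polymer=%s chirality=%s",
            tpl$sequence, tpl$polymer, tpl$chirality),
    sprintf("# captured=%s", attr(species, "captured")),
    "lineage\toffset\tadded\tcap\tpost_mm\tabundance"), con)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t%.10g",
                     species$lineage, species$offset, species$added,
                     species$cap, species$post_mm, species$abundance), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_species
#' @export
read_species <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  get_h <- function(key) {
    hit <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^# ", key, "="), "", hit[1])
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = c(added = "character"))
  df$added[is.na(df$added)] <- ""
  tmpl_line <- grep("^# template=", hdr, value = TRUE)[1]
  tf <- regmatches(tmpl_line,
                   regexec("template=([ACGT]+) polymer=(\\w+) chirality=(\\w+)",
                           tmpl_line))[[1]]
  template <- template_seq(tf[2], tf[3], tf[4])
  primers <- design_primer_set(
    template, primer_length = as.integer(get_h("primer_length")),
    chirality_preference = get_h("chirality_preference"),
    dead_fraction = as.numeric(get_h("dead_fraction")),
    loading = as.numeric(get_h("loading")),
    c_terminus = get_h("c_terminus"),
    linker_composition = ec(get_h("linker")))
  if (!identical(unname(primers$sequences[["P"]]), get_h("primer_P")))
    stop("species file header inconsistent: primer does not match template",
         call. = FALSE)
  structure(df, class = c("species_abundance", "data.frame"),
            template = template, primer_set = primers,
            captured = identical(get_h("captured"), "TRUE"))
}
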