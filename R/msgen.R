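# Synthetic centroided MALDI peak lists from species abundances: isotope
# envelopes, M+H/M+Na/M+K adducts, biotin-oxidation satellites,
# length-dependent ionization decay and seeded multiplicative noise.

#' Spectrum generator configuration
#'
#' @param adduct_fractions Named fractions for `M+H`, `M+Na`, `M+K`; must
#'   sum to 1 (proton adduct dominant in positive-mode MALDI of PNA).
#' @param oxidation_fraction Fraction of biotinylated species carrying one
#'   extra oxygen (the +16 Da biotin-oxidation satellite).
#' @param ionization_decay Multiplicative intensity factor per residue of
#'   chain length, in (0, 1]; models the lower ionization efficiency of
#'   longer sequences.
#' @param fwhm Nominal centroid peak width in Da (metadata only; output is
#'   centroided).
#' @param noise_sd Relative (lognormal) intensity noise; 0 disables noise
#'   and makes the generator fully deterministic.
#' @param min_rel_intensity Report floor relative to the most intense peak.
#' @param mz_range Optional length-2 numeric m/z window.
#' @param max_isotope_peaks Isotope peaks retained per envelope.
#' @param rng_seed Seed used when `noise_sd > 0`.
#' @return A `spectrum_config` list.
#' @export
spectrum_config <- function(adduct_fractions = c("M+H" = 0.8, "M+Na" = 0.15,
                                                 "M+K" = 0.05),
                            oxidation_fraction = 0.05,
                            ionization_decay = 0.95,
                            fwhm = 0.5,
                            noise_sd = 0.05,
                            min_rel_intensity = 1e-4,
                            mz_range = NULL,
                            max_isotope_peaks = 6L,
                            rng_seed = NULL) {
  if (length(adduct_fractions) == 0L)
    stop("adduct_fractions must not be empty", call. = FALSE)
  if (!all(names(adduct_fractions) %in% c("M+H", "M+Na", "M+K")))
    stop("adduct_fractions names must be M+H, M+Na, M+K", call. = FALSE)
  if (any(adduct_fractions < 0) || abs(sum(adduct_fractions) - 1) > 1e-8)
    stop("adduct_fractions must be in [0, 1] and sum to 1", call. = FALSE)
  if (oxidation_fraction < 0 || oxidation_fraction > 1)
    stop("oxidation_fraction must be in [0, 1]", call. = FALSE)
  if (ionization_decay <= 0 || ionization_decay > 1)
    stop("ionization_decay must be in (0, 1]", call. = FALSE)
  structure(list(adduct_fractions = adduct_fractions,
                 oxidation_fraction = oxidation_fraction,
                 ionization_decay = ionization_decay,
                 fwhm = fwhm, noise_sd = noise_sd,
                 min_rel_intensity = min_rel_intensity,
                 mz_range = mz_range,
                 max_isotope_peaks = as.integer(max_isotope_peaks),
                 rng_seed = rng_seed),
            class = "spectrum_config")
}

#' Construct a peak list
#'
#' @param mz Numeric m/z values (strictly increasing after construction).
#' @param intensity Non-negative intensities.
#' @param metadata Optional provenance list.
#' @return A `peak_list` data frame.
#' @export
peak_list <- function(mz, intensity, metadata = list()) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  ord <- order(mz)
  df <- data.frame(mz = mz[ord], intensity = intensity[ord])
  if (nrow(df) > 1L && any(diff(df$mz) <= 0)) {
    # merge coincident centroids (identical compositions collide exactly)
    grp <- cumsum(c(TRUE, diff(df$mz) > 1e-4))
    df <- data.frame(
      mz = vapply(split(df$mz * df$intensity, grp), sum, 1) /
        pmax(vapply(split(df$intensity, grp), sum, 1), 1e-300),
      intensity = vapply(split(df$intensity, grp), sum, 1))
  }
  structure(df, class = c("peak_list", "data.frame"), metadata = metadata)
}

#' Generate a synthetic centroided spectrum from species abundances
#'
#' For each species the neutral composition and isotope envelope come from
#' the composition arithmetic; one peak cluster is emitted per adduct and
#' per oxidation state.  Intensity is
#' `abundance * decay^length * adduct fraction * envelope abundance`
#' (times seeded lognormal noise if `noise_sd > 0`); peaks below the
#' relative floor are dropped and the merged, sorted list is returned.
#' Peak positions never depend on intensities, and with `noise_sd = 0` the
#' output is deterministic and independent of the seed.
#'
#' @param abundances A `species_abundance` from [run_protocol()] or
#'   [read_species()].
#' @param cfg A [spectrum_config()].
#' @param primers Primer set; defaults to the one attached to `abundances`.
#' @return A [peak_list()].
#' @export
species_to_peaks <- function(abundances, cfg = spectrum_config(),
                             primers = attr(abundances, "primer_set")) {
  if (nrow(abundances) == 0L)
    stop("species table is empty", call. = FALSE)
  if (is.null(primers))
    stop("primer set required to compute species masses", call. = FALSE)
  if (!inherits(cfg, "spectrum_config"))
    stop("cfg must be a spectrum_config", call. = FALSE)
  biotinylated <- primers$termini$c_terminus == "linker-biotin"
  ox_f <- if (biotinylated) cfg$oxidation_fraction else 0

  len <- nchar(primers$sequences[abundances$lineage]) +
    nchar(abundances$added)
  base_int <- abundances$abundance * cfg$ionization_decay^len
  # species whose strongest possible peak is far below the floor cannot
  # contribute reportable peaks; skip their envelopes
  keep <- base_int >= cfg$min_rel_intensity * max(base_int) / 20
  ab <- abundances[keep, , drop = FALSE]
  base_int <- base_int[keep]

  # fast composition path: element-count vectors on a fixed element
  # universe, with per-lineage primer compositions and a shared envelope
  # cache (species with identical compositions reuse their envelope)
  rt <- pna_residues()
  els <- sort(unique(c(unlist(lapply(rt, names)), "N", "H",
                       names(primers$termini$linker_composition %||% ec(NULL)))))
  res_vec <- vapply(rt, function(r) {
    v <- stats::setNames(numeric(length(els)), els); v[names(r)] <- r; v
  }, numeric(length(els)))
  base_vec <- vapply(names(primers$sequences), function(ln) {
    comp <- species_composition(ln, "", "amine", primers)
    v <- stats::setNames(numeric(length(els)), els); v[names(comp)] <- comp; v
  }, numeric(length(els)))
  azide_vec <- stats::setNames(numeric(length(els)), els)
  azide_vec[["N"]] <- 2; azide_vec[["H"]] <- -2  # azide minus free amine
  el_mass <- .ATOMIC_MASSES[els]
  env_cache <- new.env(parent = emptyenv())

  mzs <- numeric(0); ints <- numeric(0)
  frac <- cfg$adduct_fractions[cfg$adduct_fractions > 0]
  for (i in seq_len(nrow(ab))) {
    v <- base_vec[, ab$lineage[i]]
    if (nzchar(ab$added[i])) {
      cnt <- table(factor(strsplit(ab$added[i], "")[[1]],
                          levels = colnames(res_vec)))
      v <- v + as.numeric(res_vec %*% as.numeric(cnt))
    }
    if (ab$cap[i] == "azide") v <- v + azide_vec
    m0 <- sum(el_mass * v)
    key <- paste(v, collapse = ",")
    env <- env_cache[[key]]
    if (is.null(env)) {
      env <- isotope_envelope(ec(v), cfg$max_isotope_peaks)
      env_cache[[key]] <- env
    }
    ox_states <- if (ox_f > 0) c(0, 1) else 0
    for (ox in ox_states) {
      pop <- base_int[i] * if (ox == 0) (1 - ox_f) else ox_f
      m_ox <- m0 + ox * .ATOMIC_MASSES[["O"]]
      for (ad in names(frac)) {
        cluster_mz <- adduct_mz(m_ox, ad) + env$offset
        mzs <- c(mzs, cluster_mz)
        ints <- c(ints, pop * frac[[ad]] * env$abundance)
      }
    }
  }
  if (cfg$noise_sd > 0) {
    if (!is.null(cfg$rng_seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(cfg$rng_seed)
    }
    ints <- ints * exp(stats::rnorm(length(ints), 0, cfg$noise_sd))
  }
  floor_i <- cfg$min_rel_intensity * max(ints)
  sel <- ints >= floor_i
  if (!is.null(cfg$mz_range))
    sel <- sel & mzs >= cfg$mz_range[1] & mzs <= cfg$mz_range[2]
  peak_list(mzs[sel], ints[sel],
            metadata = list(n_species = nrow(ab),
                            noise_sd = cfg$noise_sd,
                            rng_seed = cfg$rng_seed))
}

#' Write / read a centroided peak list as TSV
#'
#' Two tab-separated columns `mz` (5 decimal places) and `intensity`;
#' header lines are prefixed `#`.  Reading validates the schema and the
#' strictly increasing m/z ordering and reports the offending line number
#' otherwise.
#'
#' @param peaks A [peak_list()].
#' @param path Destination / source path.
#' @return `read_peaklist` returns a [peak_list()]; `write_peaklist` the
#'   path, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  md <- attr(peaks, "metadata")
  writeLines("# pnaladder peaklist v1", con)
  for (k in names(md))
    if (!is.null(md[[k]]))
      writeLines(sprintf("# %s=%s", k, format(md[[k]])), con)
  writeLines("mz\tintensity", con)
  if (nrow(peaks) > 0L)
    writeLines(sprintf("%.5f\t%.8g", peaks$mz, peaks$intensity), con)
  invisible(path)
}

#' @rdname write_peaklist
#' @export
read_peaklist <- function(path) {
  lines <- readLines(path)
  is_data <- !grepl("^#", lines) & nzchar(lines)
  body <- lines[is_data]
  lineno <- which(is_data)
  if (length(body) == 0L || !identical(body[1], "mz\tintensity"))
    stop("not a pnaladder peak list (missing 'mz\\tintensity' header)",
         call. = FALSE)
  body <- body[-1]; lineno <- lineno[-1]
  if (length(body) == 0L)
    return(peak_list(numeric(0), numeric(0)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    stop("malformed peak row at line ", lineno[bad[1]], call. = FALSE)
  mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  int <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  nn <- which(is.na(mz) | is.na(int))
  if (length(nn) > 0L)
    stop("non-numeric peak row at line ", lineno[nn[1]], call. = FALSE)
  nm <- which(diff(mz) <= 0)
  if (length(nm) > 0L)
    stop("m/z not strictly increasing at line ", lineno[nm[1] + 1L],
         call. = FALSE)
  structure(data.frame(mz = mz, intensity = int),
            class = c("peak_list", "data.frame"), metadata = list())
}
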