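# Decoder: neutral-mass collapse, primer anchoring, ladder walking,
# ambiguity policy and targeted confound fixtures.

noiseless_run <- function(seed = 3, ...) {
  roundtrip(seed = seed, noise_sd = 0, ...)
}

test_that("decoder config enforces the tolerance safety bound", {
  pr <- design_primer_set(fixed_template())
  expect_error(decoder_config(pr, tolerance = 5), "tolerance")
  expect_error(decoder_config(pr, tolerance = 0), "tolerance")
  cfg <- decoder_config(pr, tolerance = 0.25)
  expect_equal(sort(names(cfg$primer_masses)),
               sort(c("P", "P-1", "P-2", "P-3")))
  # ppm mode converts at the primer-mass scale
  cfg_ppm <- decoder_config(pr, ppm = 20)
  expect_lt(abs(cfg_ppm$tolerance - max(cfg$primer_masses) * 20e-6), 1e-9)
})

test_that("adduct satellites collapse onto their parent neutral mass", {
  pr <- design_primer_set(fixed_template())
  cfg <- decoder_config(pr)
  m <- 4000
  pk <- peak_list(c(m, m + 21.98194, m + 37.95588), c(1, 0.2, 0.06))
  neu <- collapse_to_neutral(pk, cfg)
  expect_identical(nrow(neu), 1L)
  expect_equal(neu$mass, m - 1.00728, tolerance = 1e-4)
  expect_equal(neu$intensity, 1.26)
  # a single bare peak converts by the proton mass
  neu1 <- collapse_to_neutral(peak_list(1500, 1), cfg)
  expect_equal(neu1$mass, 1500 - 1.00728, tolerance = 1e-4)
})

test_that("the monoisotopic member is kept even when not the most intense", {
  pr <- design_primer_set(fixed_template())
  cfg <- decoder_config(pr)
  comp <- compose_oligomer(strrep("ACGT", 4), termini_state(
    "free-amine", "linker-biotin",
    linker_composition = default_biotin_linker()))
  env <- isotope_envelope(comp, 6)
  expect_gt(which.max(env$abundance), 1)   # peak bin is not the mono bin
  m_h <- adduct_mz(monoisotopic_mass(comp), "M+H")
  pk <- peak_list(m_h + env$offset, env$abundance)
  neu <- collapse_to_neutral(pk, cfg)
  expect_identical(nrow(neu), 1L)
  expect_equal(neu$mass, monoisotopic_mass(comp), tolerance = 1e-4)
})

test_that("anchoring needs two primers and rejects calibration drift", {
  rt <- noiseless_run()
  pr <- design_primer_set(rt$template)
  cfg <- decoder_config(pr)
  neu <- collapse_to_neutral(rt$peaks, cfg)
  anch <- anchor_primers(neu, cfg)
  expect_identical(sum(!is.na(anch)), 4L)
  # constant calibration offset beyond tolerance: hard failure
  shifted <- peak_list(rt$peaks$mz + 1.0, rt$peaks$intensity)
  expect_error(decode_spectrum(shifted, cfg), class = "pnaladder_no_anchor")
  # primer P absent: three anchors remain and decoding proceeds
  d <- as.data.frame(rt$species)
  keep <- !(d$lineage == "P" & d$added == "")
  sp2 <- structure(d[keep, ], class = class(rt$species),
                   template = attr(rt$species, "template"),
                   primer_set = attr(rt$species, "primer_set"),
                   captured = TRUE)
  pk2 <- species_to_peaks(sp2, spectrum_config(noise_sd = 0))
  read2 <- decode_spectrum(pk2, cfg)
  expect_identical(read2$n_anchors, 3L)
  expect_identical(read2$sequence, rt$expected)
})

test_that("a synthetic ladder of known increments is called correctly", {
  tpl <- fixed_template()
  pr <- design_primer_set(tpl)
  cfg <- decoder_config(pr)
  res <- residue_masses()[c("A", "C", "G", "T")]
  base_seq <- c("T", "C", "A", "G")     # includes the 266.10 -> T case
  m <- cfg$primer_masses[c("P-3", "P-2", "P-1", "P")]
  rungs <- cfg$primer_masses[["P"]] + cumsum(res[base_seq])
  neutrals <- c(sort(unname(m)), unname(rungs))
  pk <- peak_list(neutrals + 1.00728, rep(1, length(neutrals)))
  read <- decode_spectrum(pk, decoder_config(pr, max_cycles = 1))
  expect_identical(read$sequence, "TCAG")
  expect_equal(read$calls$observed_increment[1], 266.1015, tolerance = 1e-3)
  expect_true(all(abs(read$calls$increment_error_mDa) < 250))
  expect_true(all(!nzchar(read$calls$flags)))
})

test_that("noiseless round-trips recover 8/8 bases with no flags", {
  for (s in c(2, 9, 19)) {
    rt <- noiseless_run(seed = s)
    expect_identical(rt$read$sequence, rt$expected, info = paste("seed", s))
    expect_length(rt$read$flags, 0L)
    expect_equal(rt$accuracy, 1)
    # mismatch rungs are reported as minority orphans, never as calls
    expect_gt(nrow(rt$read$orphans), 0L)
    expect_lt(max(rt$read$orphans$intensity),
              max(collapse_to_neutral(rt$peaks,
                decoder_config(design_primer_set(rt$template)))$intensity))
  }
})

test_that("a missing rung truncates the read with a flag instead of guessing", {
  # perfect-match-only mixes so no parallel mismatch ladder can stand in
  # for the struck rung
  tpl <- fixed_template()
  pr <- design_primer_set(tpl)
  sp <- run_protocol(tpl, pr, list(pm_mix_for_cycle(tpl, pr, 1),
                                   pm_mix_for_cycle(tpl, pr, 2)), 2)
  peaks <- species_to_peaks(sp, spectrum_config(noise_sd = 0))
  cfg <- decoder_config(pr)
  # strike every adduct cluster of the position-3 rung species
  d <- as.data.frame(sp)
  pm3 <- d[d$lineage == "P-1" & nchar(d$added) == 4 & d$cap == "amine", ]
  m3 <- monoisotopic_mass(species_composition(pm3$lineage, pm3$added,
                                              pm3$cap, pr))
  drop <- rep(FALSE, nrow(peaks))
  for (ad in c("M+H", "M+Na", "M+K"))
    drop <- drop | (peaks$mz > adduct_mz(m3, ad) - 0.3 &
                      peaks$mz < adduct_mz(m3, ad) + 7)
  pk <- peak_list(peaks$mz[!drop], peaks$intensity[!drop])
  read <- decode_spectrum(pk, cfg)
  expected <- expected_calls(tpl)
  expect_identical(nchar(read$sequence), 2L)
  expect_true(any(grepl("missing-rung@3", read$flags)))
  expect_identical(read$sequence, substr(expected, 1, 2))
  # the intact spectrum decodes fully, confirming the fixture's surgery
  expect_identical(decode_spectrum(peaks, cfg)$sequence, expected)
})

test_that("primer-only spectra give empty reads with no false calls", {
  rt <- roundtrip(seed = 5, polymer = "DNA", chirality = "L",
                  primer_chirality = "binds-D", noise_sd = 0)
  expect_identical(rt$read$sequence, "")
  expect_identical(rt$read$n_anchors, 4L)
  expect_length(rt$read$flags, 0L)
  expect_equal(rt$accuracy, 0)
})

test_that("chirality is read off the primer set that anchors the template", {
  tplL <- template_seq(noiseless_run(seed = 12)$template$sequence, "DNA", "L")
  rtL <- roundtrip(seed = 12, template = tplL, primer_chirality = "binds-L",
                   noise_sd = 0)
  expect_identical(rtL$read$chirality, "L")
  expect_equal(rtL$accuracy, 1)
  rtX <- roundtrip(seed = 12, template = tplL, primer_chirality = "binds-D",
                   noise_sd = 0)
  expect_identical(rtX$read$sequence, "")
})

test_that("decoding is invariant to tolerance across 0.1-0.4 Da on clean input", {
  rt <- noiseless_run(seed = 8)
  pr <- design_primer_set(rt$template)
  reads <- lapply(c(0.1, 0.25, 0.4), function(tol)
    decode_spectrum(rt$peaks, decoder_config(pr, tolerance = tol))$sequence)
  expect_identical(reads[[1]], rt$expected)
  expect_identical(reads[[1]], reads[[2]])
  expect_identical(reads[[2]], reads[[3]])
})

test_that("G is still called under the oxidation confound, and A is not", {
  # C-rich read window: expected calls are G-rich
  tpl <- template_seq("CCCCCCCCATCGATCGATCGAT", "DNA", "D")
  rt <- roundtrip(seed = 21, template = tpl, noise_sd = 0,
                  oxidation_fraction = 0.1)
  expect_identical(rt$read$sequence, strrep("G", 8))
  expect_equal(rt$accuracy, 1)
  # T-rich window decodes to A calls: the +16 satellites of the A rungs
  # must not be promoted to G calls
  tplA <- template_seq("TTTTTTTTATCGATCGATCGAT", "DNA", "D")
  rtA <- roundtrip(seed = 22, template = tplA, noise_sd = 0,
                   oxidation_fraction = 0.1)
  expect_identical(rtA$read$sequence, strrep("A", 8))
})
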