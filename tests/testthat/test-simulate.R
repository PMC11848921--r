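# Kinetic simulator: capture gating, conversion kinetics, mismatch
# competition, cycling, conservation and the stochastic cross-check.

test_that("templates and primer sets enforce the chirality rules", {
  expect_error(template_seq("ACGT", "PNA", "D"), "achiral")
  expect_error(template_seq("ACGT", "DNA", "achiral"), "D or L")
  tpl <- fixed_template()
  pr <- design_primer_set(tpl)
  expect_identical(unname(pr$sequences[["P"]]),
                   pna_complement(substr(tpl$sequence, 9, 22)))
  # P-k removes k residues from the N-terminus (the string tail, C-to-N)
  for (k in 1:3)
    expect_identical(unname(pr$sequences[[paste0("P-", k)]]),
                     substr(pr$sequences[["P"]], 1, 14 - k))
})

test_that("capture requires matching chirality and complementarity", {
  tplL <- template_seq("TTAATGACATCGATCGATCGAT", "DNA", "L")
  prL <- design_primer_set(tplL, chirality_preference = "binds-L")
  prD <- design_primer_set(tplL, chirality_preference = "binds-D")
  expect_true(check_capture(tplL, prL)$captured)
  expect_false(check_capture(tplL, prD)$captured)
  # achiral PNA template is captured by either primer chirality
  tplP <- template_seq("TTAATGACATCGATCGATCGAT", "PNA")
  expect_true(check_capture(tplP, design_primer_set(
    tplP, chirality_preference = "binds-D"))$captured)
  expect_true(check_capture(tplP, design_primer_set(
    tplP, chirality_preference = "binds-L"))$captured)
  # non-complementary primer: decision is no-capture, not an error
  other <- design_primer_set(fixed_template())
  other$sequences[["P"]] <- strrep("A", 14)
  expect_false(check_capture(tplL, other)$captured)
})

test_that("extension conversion follows first-order kinetics with hydrolysis", {
  expect_equal(extension_conversion(0, 2), 0)
  expect_equal(extension_conversion(2, 2), 0.5)
  expect_equal(extension_conversion(4, 2), 0.75)
  expect_error(extension_conversion(-1, 2), ">= 0")
  # hydrolysis of the ester pool lowers the effective conversion
  expect_lt(extension_conversion(4, 2, 300), 0.75)
  expect_gt(extension_conversion(4, 2, 300), 0.7)
  # monotone non-decreasing in time
  conv <- extension_conversion(seq(0, 30, by = 0.5), 2, 300)
  expect_true(all(diff(conv) >= 0))
})

test_that("competition weights implement the mismatch taxonomy", {
  cfg <- kinetics_config()
  window <- "TGAC"
  pm <- pna_complement(window)          # GTCA
  mm_t <- "GTCT"                        # single N-terminal (distal) mismatch
  mm_c <- "TTCA"                        # single C-terminal mismatch
  mm_i <- "GACA"                        # single internal mismatch
  mm_2 <- "GAAA"                        # multiple mismatches
  mix <- reagent_mix(c(pm, mm_t, mm_c, mm_i, mm_2), conc_uM = 3)
  w <- competition_weights(window, mix, cfg)
  expect_equal(unname(w[pm]), 1)
  expect_equal(unname(w[mm_t]), cfg$terminal_mm_weight)
  expect_equal(unname(w[mm_c]), cfg$terminal_mm_weight)
  expect_equal(unname(w[mm_i]), cfg$internal_mm_weight)
  expect_equal(unname(w[mm_2]), cfg$multi_mm_weight)
  # adding the complements sequesters the mismatch 4-mer
  mix_cm <- reagent_mix(c(pm, mm_t, pna_complement(pm), pna_complement(mm_t)),
                        conc_uM = 3)
  w_cm <- competition_weights(window, mix_cm, cfg)
  expect_equal(unname(w_cm[pm] / w_cm[mm_t]),
               1 / cfg$cm_sequestration_factor)  # 4:1
  # helper presence divides mismatch weights, not the perfect match
  w_h <- competition_weights(window, mix_cm, cfg, helper_present = TRUE)
  expect_equal(unname(w_h[pm]), 1)
  expect_equal(unname(w_h[mm_t] * cfg$helper_factor), unname(w_cm[mm_t]))
})

test_that("a terminal mismatch competes 1:1 without CMs and 4:1 with CMs", {
  tpl <- fixed_template()
  pr <- design_primer_set(tpl, dead_fraction = 0.3)
  pm <- "GTCA"; mm <- "GTCC"
  sp1 <- run_protocol(tpl, pr, reagent_mix(c(pm, mm), conc_uM = 3),
                      n_cycles = 1)
  d1 <- as.data.frame(sp1)
  r1 <- d1$abundance[d1$lineage == "P" & d1$added == pm] /
    d1$abundance[d1$lineage == "P" & d1$added == mm]
  expect_equal(r1, 1, tolerance = 1e-12)
  sp4 <- run_protocol(tpl, pr,
                      reagent_mix(c(pm, mm, pna_complement(pm),
                                    pna_complement(mm)), conc_uM = 3),
                      n_cycles = 1)
  d4 <- as.data.frame(sp4)
  r4 <- d4$abundance[d4$lineage == "P" & d4$added == pm] /
    d4$abundance[d4$lineage == "P" & d4$added == mm]
  expect_equal(r4, 4, tolerance = 1e-12)
  # two or more mismatches: essentially no product
  mm2 <- "GAAC"
  sp0 <- run_protocol(tpl, pr, reagent_mix(c(pm, mm2), conc_uM = 3),
                      n_cycles = 1)
  d0 <- as.data.frame(sp0)
  expect_length(d0$abundance[d0$lineage == "P" & d0$added == mm2], 0)
})

test_that("post-mismatch strands extend 6-fold less in the next cycle", {
  tpl <- fixed_template()
  pr <- design_primer_set(tpl, dead_fraction = 0.3)
  pm <- "GTCA"; mm <- "GTCC"
  next_pm <- pna_complement("TTAA")
  sp <- run_protocol(tpl, pr,
                     list(reagent_mix(c(pm, mm), conc_uM = 3),
                          reagent_mix(next_pm, conc_uM = 3)),
                     n_cycles = 2)
  d <- as.data.frame(sp)
  a_pm <- d$abundance[d$lineage == "P" & d$added == paste0(pm, next_pm)]
  a_mm <- d$abundance[d$lineage == "P" & d$added == paste0(mm, next_pm)]
  expect_equal(a_pm / a_mm, kinetics_config()$post_mm_extension_penalty,
               tolerance = 1e-12)
})

test_that("cycling produces the expected species and conserves lineages", {
  tpl <- fixed_template()
  pr <- design_primer_set(tpl, dead_fraction = 0.3)
  mixes <- list(pm_mix_for_cycle(tpl, pr, 1), pm_mix_for_cycle(tpl, pr, 2))
  sp <- run_protocol(tpl, pr, mixes, n_cycles = 2)
  d <- as.data.frame(sp)
  # 12 distinct species: 4 primers + 4 cycle-1 + 4 cycle-2 products
  expect_identical(nrow(d), 12L)
  expect_identical(sum(nchar(d$added) == 0), 4L)
  expect_identical(sum(nchar(d$added) == 4), 4L)
  expect_identical(sum(nchar(d$added) == 8), 4L)
  # every primer extended by exactly 8 residues over two PM-only cycles
  expect_true(all(d$cap[nchar(d$added) == 8] == "azide"))
  # abundance conservation within each primer lineage
  for (ln in names(pr$sequences))
    expect_equal(sum(d$abundance[d$lineage == ln]), pr$loading,
                 tolerance = 1e-9)
  # consecutive ladder products differ by exactly one residue composition
  masses <- vapply(seq_len(nrow(d)), function(i) monoisotopic_mass(
    species_composition(d$lineage[i], d$added[i], d$cap[i], pr)),
    numeric(1))
  ord <- order(masses)
  gaps <- diff(masses[ord])
  res <- residue_masses()[c("A", "C", "G", "T")]
  cap_d <- -terminator_delta()
  ok <- vapply(gaps, function(g)
    any(abs(g - res) < 1e-6) || any(abs(g - res - cap_d) < 1e-6),
    logical(1))
  expect_true(all(ok))
})

test_that("degenerate protocols behave as documented", {
  tpl <- fixed_template()
  pr <- design_primer_set(tpl, dead_fraction = 0.3)
  mix <- pm_mix_for_cycle(tpl, pr, 1)
  # zero reaction time: state unchanged
  sp0 <- run_protocol(tpl, pr, mix, n_cycles = 1,
                      cfg = kinetics_config(reaction_time = 0))
  expect_true(all(nchar(as.data.frame(sp0)$added) == 0))
  # fully hydrolyzed mix: warning and no extension
  dead_mix <- reagent_mix("GTCA", conc_uM = 3, activation = "hydrolyzed")
  expect_warning(sph <- run_protocol(tpl, pr, dead_mix, n_cycles = 1),
                 "hydrolyzed")
  expect_true(all(nchar(as.data.frame(sph)$added) == 0))
  # mismatched chirality: primers only
  tplL <- template_seq(tpl$sequence, "DNA", "L")
  spL <- run_protocol(tplL, design_primer_set(tplL,
                                              chirality_preference = "binds-D"),
                      mix, n_cycles = 2)
  expect_true(all(nchar(as.data.frame(spL)$added) == 0))
  expect_false(attr(spL, "captured"))
})

test_that("PM:MM ratio responds monotonically to sequestration and helper", {
  cfg_base <- kinetics_config()
  window <- "TGAC"
  mk <- function(cm, helper) {
    cfg <- kinetics_config(cm_sequestration_factor = cm)
    mix <- reagent_mix(c("GTCA", "GTCT", pna_complement("GTCA"),
                         pna_complement("GTCT")), conc_uM = 3)
    w <- competition_weights(window, mix, cfg, helper_present = helper)
    unname(w[["GTCA"]] / w[["GTCT"]])
  }
  ratios <- vapply(c(1, 0.5, 0.25, 0.1), mk, numeric(1), helper = FALSE)
  expect_true(all(diff(ratios) > 0))
  expect_gt(mk(0.25, TRUE), mk(0.25, FALSE))
})

test_that("stochastic mode agrees with expectation mode within 3 SE at n = 1e5", {
  tpl <- fixed_template()
  pr <- design_primer_set(tpl, dead_fraction = 0.3)
  mixes <- list(pm_mix_for_cycle(tpl, pr, 1), pm_mix_for_cycle(tpl, pr, 2))
  n <- 1e5
  exp_sp <- as.data.frame(run_protocol(tpl, pr, mixes, n_cycles = 2))
  sto_sp <- as.data.frame(run_protocol(tpl, pr, mixes, n_cycles = 2,
                                       mode = "stochastic",
                                       n_molecules = n, seed = 99))
  key <- function(d) paste(d$lineage, d$added, d$cap)
  for (i in seq_len(nrow(exp_sp))) {
    f <- exp_sp$abundance[i]           # expected fraction of the lineage
    j <- match(key(exp_sp)[i], key(sto_sp))
    obs <- if (is.na(j)) 0 else sto_sp$abundance[j] / n
    se <- sqrt(f * (1 - f) / n)
    expect_lt(abs(obs - f), 3 * se + 1e-12,
              label = sprintf("species %s: |%.5f - %.5f|", key(exp_sp)[i],
                              obs, f))
  }
})
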