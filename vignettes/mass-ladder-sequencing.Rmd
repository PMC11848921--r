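---
title: "Enzyme-free PNA primer-extension sequencing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzyme-free PNA primer-extension sequencing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnaladder)
```

## The problem

Enzyme-free sequencing by templated synthesis reads a nucleic-acid template
without polymerases: a biotinylated peptide nucleic acid (PNA) primer
captures the template, and activated PNA 4-mers ligate to the primer's free
N-terminal amine wherever they hybridize adjacent to it, complementary to
the next four template bases. An N-terminal azide on every 4-mer acts as a
reversible terminator — exactly one 4-mer adds per cycle — and is reduced
back to an amine (Staudinger reduction) between cycles. Because the
chemistry only requires hybridization and amide-bond formation, the same
reaction sequences d-DNA, its mirror image l-DNA, LNA and PNA
templates; chirality selectivity comes entirely from the primer.

A four-nucleotide step per cycle would be useless for base-resolved
reading. The trick is the *primer deletion ladder*: the primer P is used
together with its N-terminal deletions P−1, P−2, P−3. Their extension
products end on four consecutive template positions, so the sorted product
masses form a ladder whose successive gaps are *single residue masses*.
Reading the gaps in a MALDI-TOF spectrum reads the sequence:

- aeg-PNA residue masses (Da): A 275.1131, C 251.1018, G 291.1080,
  T 266.1015;
- the minimum pairwise gap is A−T = 9.01 Da, far above instrument
  tolerance;
- the one designed degeneracy is G = A + O *exactly* (15.9949 Da), which
  collides with the +16 Da biotin-oxidation satellite (see below).

`pnaladder` implements the full desk-scale counterpart of this workflow:
exact mass arithmetic (`chem` functions), 4-mer library combinatorics, a
kinetic simulator of the cyclic extension, a synthetic centroided MALDI
peak-list generator, and the ladder decoder.

## Mass arithmetic

All masses derive from integer elemental compositions (`ec()`) and a pinned
IUPAC atomic-mass/isotope table, never from cached floating-point sums.
Residue compositions follow the standard N-(2-aminoethyl)glycine backbone
with a base-acetyl linker; they are user-overridable
(`load_residue_table()`) and are validated in the test suite against an
independent atom-count oracle assembled from the structural groups of the
drawn residue. Serine-modified residues (lowercase letters) add CH2O; the
alpha- versus gamma-position question is mass-silent and deliberately left
open. The biotin linker at the primer C-terminus is a synthetic stand-in
composition (`default_biotin_linker()`, biotin + AEEA-type spacer + amide):
only its mass matters and it cancels in every ladder difference. All ions
are treated as singly charged, the observed regime for linear positive-mode
MALDI of 3–6 kDa PNA.

Isotope envelopes are computed by per-element polynomial convolution on an
extra-neutron grid, abundances normalized over the untruncated
distribution; the suite checks them against an exhaustive multinomial
enumeration to 1e-9 on small molecules.

## The kinetic model

The simulator propagates population fractions (expectation mode; MALDI
intensities are population averages), with a seeded per-molecule stochastic
mode used as an internal cross-check (the two agree within 3 standard
errors at 10^5 molecules per primer).

**Conversion.** Extension is first order, `1 − 2^(−t/t_half)`, with
`t_half = 2` min at the reference 3 uM s-NHS-ester concentration and
`t = 4` min per cycle, so one cycle converts 75% of the reactive primer.
Hydrolysis of the activated ester (half-life 300 min) competes as a
parallel first-order channel on the reagent pool, trimming this slightly.
The templated site is treated as *saturating*: the rate uses
`min(1, sum of competition weights)`, so adding more competing 4-mers
redistributes — rather than accelerates — conversion. The calibrated
half-life refers to the standard protocol in which the downstream adjacent
4-mer (the "helper") is available; a missing helper divides the rate by
`helper_factor` (default 2). This choice keeps the measured half-life an
invariant of the model rather than a moving target of mix composition.

**Fidelity.** Competing 4-mers are classified against the perfect match
for the current template window: single *terminal* mismatches (either end
of the 4-mer; the two ends share one weight unless overridden) incorporate
with weight 1.0 relative to the perfect match — the experimentally
ambiguous 1:1 case; a single internal mismatch gets 0.01 (trace level;
internal mismatches disrupt pi-stacking across the duplex); two or more
mismatches get 0. When a mismatch 4-mer's antiparallel complement is
present in the mix, solution-phase sequestration into the 4-mer:4-mer
duplex multiplies its weight by 0.25, moving the product ratio to 4:1 —
which is why complement-closed libraries (every member with its partner)
are the recommended design, enforced by `build_paired_sublibrary()`.
Sequestration is a single multiplicative factor rather than an explicit
duplex equilibrium: the available ratio data do not constrain a full
equilibrium model non-circularly, though `K_D` and `k_off` are retained in
the configuration for a future explicit mode.

**Error propagation.** A strand whose last addition carried a terminal
mismatch extends in the next cycle with its conversion divided by
`post_mm_extension_penalty = 6`, reproducing the observed 6:1
second-cycle extension ratio. The penalty acts on the incorporated
fraction, not on the rate constant: the calibration point is a product
ratio, and a rate-constant penalty would make the ratio drift with
reaction time instead of sitting at 6:1 under the default timing.

**Capture.** Primer binding is modeled as binary (the 14-mer capture
duplex is far above its melting regime): capture succeeds iff the template
is achiral (PNA) or the primer set's chirality preference matches the
template chirality, and the primer complements the capture site. A failed
capture returns unreacted primers, not an error — the empty read is the
scientifically meaningful result and is how template chirality is
determined.

A `dead_fraction` (default 0.3) of each primer never extends, emulating the
unreactive bead-bound population; it guarantees the four anchor peaks the
decoder starts from, so it is a feature of the protocol, not merely noise.

## The spectrum generator

Each simulated species contributes one isotope cluster per adduct (default
fractions M+H 0.8, M+Na 0.15, M+K 0.05 — configurable; only the qualitative
proton dominance is constrained by observation) and, for biotinylated
species, an oxidation satellite cluster at +15.9949 Da carrying
`oxidation_fraction` (default 0.05) of the population. Intensity is
`abundance × decay^length × adduct fraction × envelope abundance` with
`decay = 0.95` per residue emulating the poorer ionization of longer
oligomers. Noise is multiplicative lognormal (shot-to-shot variation in
MALDI is relative), seeded, and applied to intensities only; peak
*positions* are exact. Output is centroided (the decoder consumes
centroids; profile mode is out of scope). Peaks below `min_rel_intensity`
(1e-4 of the base peak) are dropped.

What the generator does *not* emulate: m/z calibration drift and jitter,
matrix cluster ions, detector saturation, baseline chemical noise, and
charge states beyond +1. Passing round-trips therefore demonstrate the
correctness of the ladder logic and the robustness margins against
intensity perturbation and satellite interference — not performance on raw
instrument data, which would additionally require recalibration and
profile-mode peak picking.

## The decoder

Decoding proceeds in three stages:

1. **Collapse to neutrals.** Isotope envelopes are extracted greedily:
   clusters seed at the most intense unassigned peak and claim members one
   13C spacing (±8 mDa) at a time in both directions. Seeded walking —
   rather than chaining adjacent gaps — keeps interleaved envelopes of
   near-isobaric species apart, which matters in the 256-member regime
   where minority mismatch products crowd the spectrum. The monoisotopic
   (lightest) member represents the cluster even when a heavier isotope is
   more intense, as it is for species above ~2.5 kDa. Na/K satellites are
   folded into their M+H parent only when the offset matches the exact
   adduct constant within 20 mDa *and* the satellite is fainter than 0.6×
   the parent; both guards prevent a genuine ladder rung from being
   swallowed by an unrelated peak one adduct offset below it.

2. **Anchor the primers.** The four declared primer masses are matched
   within tolerance. At least two anchors are required; fewer (e.g. under
   a constant calibration offset beyond tolerance — recalibration is out
   of scope) is a hard failure with its own condition class.

3. **Walk the ladder.** From the full primer's mass, each step seeks a
   peak one residue mass up, with a one-time optional azide-cap delta
   (+25.9905 Da) marking the transition from the reduced intermediate
   block to the final-cycle azide-capped block (the default assumes no
   post-run reduction; configurable). Among matching candidates the most
   intense peak wins. This single rule also resolves the G-versus-A+16
   confound: a genuine G rung is brighter than the faint oxidation
   satellite of an A rung (5% by default), and a genuine A rung is
   brighter than its mismatch-G sibling; when an annotated oxidation
   satellite matches a G call that wins over the A interpretation by less
   than 1.5x — far under the normal mismatch margin — the call is flagged
   `oxidation-confounded` rather than trusted. A gap
   matching no residue truncates the read; if a two-residue gap to a real
   peak explains the break, the position is flagged `missing-rung`. The
   decoder never guesses: primer-only spectra yield empty reads, and all
   unexplained peaks are reported as orphans with their intensities.

The default mass tolerance is 0.25 Da (linear MALDI-TOF at 3–6 kDa); a ppm
mode is available. Construction asserts tolerance < 4.5 Da (half the A−T
gap) so residue increments stay separable, and on clean input decoding is
invariant over 0.1–0.4 Da.

## Problem sizes and numerical choices

The test suite exercises the sizes the package is designed for: 22-nt
templates (14-mer primer + two cycles x 4 positions = 8 calls), the full
256-member library, 200 seeded noiseless round-trips across
DNA-D/DNA-L/LNA/PNA and 100 noisy round-trips (lognormal intensity noise,
dead fraction 0.2–0.6, oxidation up to 0.1) — the noiseless set must
recover 8/8 bases everywhere, the noisy set at least 95% per base.
Species below 1e-9 of a primer loading are pruned during simulation;
isotope convolution is truncated at 31 extra-neutron bins (beyond any
abundance relevant at these masses, and never renormalized); envelopes are
cached per composition.

## Known limitations

- Primer residues default to unmodified aeg. Serine-modified primers with
  unmodified 4-mer reagents would break the single-residue ladder
  arithmetic (the residue at a template position must weigh the same
  whether it came from a primer or an extension); modified residues are
  supported in the tables but the ladder then needs matched reagents.
- Mismatch position dependence is collapsed to terminal/internal/multiple;
  finer position effects are config-extensible but not defaulted.
- No mixture deconvolution of co-captured distinct templates, no read
  lengths beyond the configured cycle count, no negative-ion mode.
- The AT-only regime (weak pairing) is generated as a flagged fixture but
  the fidelity weights are not specialized for it.

## Reproducing the headline numbers

```{r, eval = FALSE}
# combinatorics
length(enumerate_full_repertoire())                       # 256
nrow(build_paired_sublibrary(c("AxxC","GxxT","CxxA","TxxG")))  # 64
imaging_density(50)                                       # 40000

# a complete round-trip
rt <- roundtrip(seed = 1, noise_sd = 0)
rt$expected; rt$read$sequence; rt$accuracy
```

`scripts/acceptance.R` recomputes all of these plus the 1:1 / 4:1 / 6:1
fidelity calibrations and the +16 Da satellite offset from a fresh run of
the installed package.
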