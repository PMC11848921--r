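# pnaladder

Simulation and decoding toolkit for **enzyme-free sequencing of DNA and
xeno nucleic acids (XNA) by PNA templated synthesis**, read out as a
MALDI-TOF mass ladder.

## The science

A biotinylated 14-mer peptide nucleic acid (PNA) primer captures a
template (d-DNA, l-DNA, LNA or PNA) on streptavidin beads.
C-terminally activated PNA **4-mers** — carrying an N-terminal azide as a
reversible terminator — ligate to the primer's free amine wherever they
hybridize adjacent to it, adding exactly four complementary residues per
cycle; trimethylphosphine reduction of the azide re-arms the chain for the
next cycle. Using the primer **P together with its N-terminal deletions
P−1, P−2, P−3** makes the four product ladders interleave so that
consecutive product masses differ by a *single* residue:

| residue | monoisotopic mass (Da) |
|---|---|
| C | 251.1018 |
| T | 266.1015 |
| A | 275.1131 |
| G | 291.1080 |

so each gap in the centroided spectrum is a base call
(`mass increment → base`). The minimum gap (A−T) is 9.01 Da; the one
designed degeneracy is G = A + O exactly, which collides with the +16 Da
biotin-oxidation satellite and is resolved by intensity evidence. Because
no enzyme is involved, the same chemistry reads both DNA enantiomers (the
primer chirality gates capture, so an empty read *is* the chirality
assay), LNA, and PNA.

The package implements, desk-scale and fully seeded:

- **chem** — exact elemental-composition arithmetic, monoisotopic masses,
  isotope envelopes (polynomial convolution), MALDI adducts, terminator
  delta;
- **library** — the 256-member 4-mer repertoire, antiparallel PNA
  complementation, complement-closed sublibrary design (`AxxC:GxxT`,
  `CxxA:TxxG`);
- **simulate** — cyclic extension kinetics with mismatch competition,
  complementary-match sequestration (1:1 → 4:1), post-mismatch extension
  penalty (6:1), helper effect, hydrolysis, dead primer fraction,
  expectation and stochastic modes;
- **msgen** — synthetic centroided peak lists with isotope envelopes,
  M+H/M+Na/M+K adducts, +16 Da oxidation satellites, length-dependent
  ionization decay and seeded lognormal noise;
- **decode** — envelope collapse, primer anchoring, ladder walking with a
  strict no-guessing policy (flags and truncation instead of calls without
  mass evidence);
- **cli** — file-composable commands plus a seeded fixture generator
  (`exec/pnaladder`).

## Worked example

```r
library(pnaladder)
rt <- roundtrip(seed = 1, noise_sd = 0)   # simulate -> spectrum -> decode
rt$template$sequence
#> [1] "ATGACAGGCCGGAAACCCCGAG"
rt$expected
#> [1] "CCTGTCAT"
rt$read
#> <sequence_read>
#>   anchors found : 4/4
#>   chirality tag : D (from primer set)
#>   read (C->N)   : CCTGTCAT  (8 calls)
#>   per-call evidence:
#>      1  C  + 251.1018 Da  (  +0.0 mDa, P-3)
#>      2  C  + 251.1018 Da  (  +0.0 mDa, P-2)
#>      3  T  + 266.1015 Da  (  -0.0 mDa, P-1)
#>      4  G  + 291.1080 Da  (  -0.0 mDa, P)
#>      5  T  + 292.0920 Da  (  +0.0 mDa, P-3)
#>      6  C  + 251.1018 Da  (  -0.0 mDa, P-2)
#>      7  A  + 275.1131 Da  (  +0.0 mDa, P-1)
#>      8  T  + 266.1015 Da  (  +0.0 mDa, P)
#>   orphan peaks  : 294
rt$accuracy
#> [1] 1
```

Eight base calls over two cycles: the first four rungs are the reduced
(free-amine) cycle-1 leftovers of P−3…P, the fifth increment carries the
one-time azide-cap delta (266.10 + 25.99 = 292.09 Da) marking the
transition into the azide-capped final-cycle block, and every minority
mismatch product lands in the orphan list, never in a call. The read is
the PNA complement, C→N, of the template bases 5′ of the primer footprint.

The same pipeline from a shell (the script installs under the package's
`exec/` directory; from a checkout just use `Rscript exec/pnaladder`):

```sh
Rscript exec/pnaladder library --out mix.tsv --full   # 256-member reagent mix
Rscript exec/pnaladder roundtrip --seed 1 --noise 0   # accuracy=1.000
Rscript exec/pnaladder fixtures --dir fx --seed 7     # reproducible fixture sets
```

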