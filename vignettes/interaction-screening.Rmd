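---
title: "Length-calibrated PAE screening of predicted protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-calibrated PAE screening of predicted protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spryscreen)
```

## The problem and the model

A structure predictor given two protein sequences returns, besides
coordinates, a predicted aligned error (PAE) matrix: entry $(i, j)$ is
the expected positional error (Å) of residue $i$ when the model is
aligned on residue $j$. Within a confidently folded chain these values
are small; between two chains they are small *only if the predictor is
confident about the relative placement of the chains* — that is, about
the interface. This makes the inter-chain PAE blocks a usable interaction
signal even for complexes that are too transient to survive biochemical
purification, such as E3 ligase–substrate pairs that end in degradation.

`spryscreen` condenses that signal into one number per bait–prey pair:

1. **Reversal.** Every PAE entry is mapped to $E_{\max} - E_{ij}$, where
   $E_{\max}$ is the dialect's error ceiling (31.75 Å unless the file
   states otherwise). Subtraction, not a reciprocal, is used: it keeps
   units (Å), is bounded, zero at the ceiling, and linear, so the
   downstream sum behaves as a monotone "interface mass".
2. **Observed contacts (OC).** The grand sum of reversed PAE over both
   rectangular inter-chain blocks. PAE is asymmetric and nothing in the
   signal privileges a direction, so both blocks are summed; this makes
   OC and the score invariant to relabeling bait and prey, which the
   test suite checks as a property. Intra-chain entries are excluded by
   construction — they measure fold confidence, not interaction.
3. **Expected contacts (EC).** OC grows with chain lengths for purely
   geometric reasons (the blocks are bigger), so raw OC cannot be
   compared across pairs. EC is a linear background model,
   `EC = 243.9 × length + 279,484`, obtained by ordinary least squares
   on a proteome-wide single-bait screen; the package ships these
   coefficients as `default_calibration()` and refits with
   `fit_calibration()` when the user has their own screen.
4. **Score and call.** `score = OC / EC`, so background sits near 1 and
   high-confidence pairs exceed a strict cutoff of 2.5 — the level that
   separates well-characterized SPRY–sensor interactions from the bulk.
   The comparison is strictly greater-than on the raw floating value;
   rounding happens only in output formatting.

### Score orientation

The ratio is sometimes described in the inverted orientation (expected
over observed). Only OC/EC gives the working semantics — background ≈ 1
*and* strong interfaces above the cutoff — so OC/EC is the default, and
`interaction_score(..., orientation = "ec_over_oc")` (config key
`score_orientation`) exists for the inverted convention. This is a
deliberate design decision, not an oversight.

### Calibration length

Whether "length" in the calibration means the prey alone or both chains
combined is ambiguous when the calibration screen fixes a single bait:
the two definitions then differ only by a constant shift absorbed by
the intercept. The package defaults to `combined`, which generalizes to
screens with varying baits, and offers `prey_only`
(`ec_length_definition`). An EC ≤ 0 — possible when extrapolating a
refitted line far below its data — raises a classed error rather than
silently producing a negative denominator.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `max_pae_default` | 31.75 | Å | conventional predictor ceiling, used when a file omits it |
| `threshold` | 2.5 | — | strict high-confidence cutoff; benchmarked on known interactions |
| `ec_slope`, `ec_intercept` | 243.9, 279,484 | reversed-PAE units | published single-bait calibration; any refit overrides |
| `contact_cutoff` | 5.0 | Å | common heavy-atom contact convention |
| `salt_bridge_cutoff` | 4.0 | Å | N–O distance for Asp/Glu carboxylate vs Lys/Arg side-chain N |
| `polar_cutoff` | 3.5 | Å | donor/acceptor heavy-atom distance |
| `identity_denominator` | alignment | — | gaps count against percent identity; `shorter_sequence` available |
| `min_common_baits` | 3 | — | minimum overlap for a defined profile correlation |

## Residue-level interface analysis

Contacts are computed from coordinates, not from PAE: a residue pair is
in contact when its minimum heavy-atom distance is at or below the
cutoff, and the recorded distance is that true minimum. An optional
`pae_filter` additionally requires both directional PAE entries of the
residue pair to be below a ceiling, restricting the interface to
confidently placed pairs — useful because a geometric contact in a
low-confidence region is weak evidence. Classification is deliberately
narrow: salt bridges only between Asp/Glu carboxylate oxygens and
Lys/Arg side-chain nitrogens (His and the free N-terminal amine are
excluded by default; the reported electrostatic pairs in this family
are all Asp/Glu ↔ Arg/Lys side-chain interactions), polar for any other
N/O pair within 3.5 Å including backbone atoms (so a side-chain amide
against a backbone carbonyl counts), generic otherwise. There is no
hydrogen placement and no angular criterion; the rules are distance-only
and symmetric.

Domain mapping uses 1-based inclusive coordinates (the "404–630aa"
construct convention), with both boundary residues inside. The headline
statistic, `spry_fraction`, is the fraction of *distinct* prey-side
contact residues inside the prey's SPRY annotation; with no contacts it
is reported absent (`NA`), never 0.

## Profile analytics

A binding profile is one prey's score vector across baits. Profile
similarity is Pearson correlation over shared baits, defined only with
at least 3 common baits and non-constant profiles — undefined entries
are `NA`, never coerced to 0. Percent identity uses global alignment
with BLOSUM62 and affine gaps (open 10, extend 0.5) via Biostrings;
identity percentages depend on these conventions, which is why they are
config-exposed and why no exact published identity figure is asserted
in tests. Full-length versus SPRY-only concordance is per-prey Spearman
correlation (average ranks on ties), summarized as a frequency
histogram over $[-1, 1]$ in 0.1 bins.

## Chimera construction

`build_chimera()` concatenates donor segments at 1-based inclusive
boundaries with no linker by default (direct swaps; a linker string is
available for generality). Every output position carries a
`(source, source_index)` provenance record, emitted into the FASTA
description line and parsed back exactly, so downstream interface
analyses can attribute contacts to donor proteins. Junctions beyond the
stated RING/SPRY boundaries (e.g. coiled-coil segment limits) are not
guessed: such specs must be user-supplied.

## What the synthetic generator emulates — and what it does not

`make_pae_fixture()` plants `k = round(f·L_a·L_b)` low-PAE cells
(symmetrically, in both inter-chain blocks) on a uniform background, so
noiseless fixtures have a closed-form OC the pipeline must reproduce to
10⁻⁹ relative — this closes the loop between generator and scorer with
independent arithmetic. Gaussian noise is clipped to $[0, E_{\max}]$
and voids the closed form (noisy fixtures serve statistical tests
only). `make_structure_fixture()` places planted atom pairs at exact
axis-aligned distances with three-decimal coordinates, so PDB and mmCIF
emissions reproduce distances to 10⁻⁶ Å; all other atoms are offset at
least 6 Å further, and decoys sit at least 2 Å beyond the cutoff from
the opposite chain.

None of this mimics real predictor error textures: no pLDDT coupling,
no domain-shaped PAE blocks, no realistic side-chain geometry. Passing
tests therefore demonstrate the *arithmetic and contracts* of the
pipeline, not the biological accuracy of any particular prediction run.
Real screens inherit whatever biases the upstream predictor has —
oligomeric proteins and interactions mediated by few residues or third
partners are known weak spots.

## Numerical choices and degenerate inputs

- Scoring sums are plain double-precision matrix sums; no compensated
  summation is needed at screen scale (blocks ≤ ~10⁶ entries with
  entries ≤ 31.75).
- Tie-breaking in rank selection of models: the lowest rank wins; among
  files with equal rank the first in lexicographic order is taken.
- A partition hint conflicting with chain ids encoded in an AF3 file is
  an error, not a warning — a wrong partition silently corrupts OC.
- Degenerate calibration inputs (fewer than 2 distinct lengths) and
  empty interfaces (zero contact residues for a fraction) raise classed
  errors; callers can catch them by class.
- Unknown residue names become `X` with a warning; unknown PAE dialects
  are rejected rather than guessed.
- Output tables are written with 6 significant digits and canonical
  (bait, prey) ordering, which is what makes reruns byte-identical.

## Problem sizes used in the test suite

The suite and the acceptance script run on deliberately small problems:
chains up to 50 residues for the oracle equivalences (100 random PAE
fixtures, 50 noiseless planted fixtures, 50 toy structures), a 20-point
calibration grid, 200-pair null simulations, and 6-pair screen
directories. These sizes were chosen so that the brute-force oracles —
O(n²) double loops and all-against-all atom scans — remain trivially
fast while still exercising every code path; the quantities being
checked (exact sums, closed forms, rank statistics) do not become more
informative at larger n.

## Known limitations

- No ipTM/pDockQ/pTM-based scoring variants; the score is the grand-sum
  OC/EC ratio only.
- No solvent-accessibility, buried-surface, hydrogen-bond-angle,
  π-stacking or cation-π analysis.
- Binary or pickled PAE formats and multi-model NMR files are out of
  scope; exactly three JSON dialects are supported.
- The screen scores only the top-ranked model per pair; model ensembles
  are not aggregated.
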