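---
title: "Methods: HGL-DTG dereplication, chemotyping and candidate discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HGL-DTG dereplication, chemotyping and candidate discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgldtg)
```

## The measurement model

HGL-DTGs share one aglycone, 17-hydroxygeranyllinalool (C20H34O2,
monoisotopic mass 306.2559 Da), decorated with three residue types whose
attachment each removes one water: hexose (glucose, residue C6H10O5,
162.0528 Da), deoxyhexose (rhamnose, C6H10O4, 146.0579 Da) and malonyl
(C3H2O3, 86.0004 Da). A compound is therefore summarized — up to positional
isomerism, which mass cannot resolve — by the residue counts
$(n_{hex}, n_{dhex}, n_{mal})$, with neutral formula

$$\mathrm{C_{20}H_{34}O_2} + n_{hex}\,\mathrm{C_6H_{10}O_5} +
  n_{dhex}\,\mathrm{C_6H_{10}O_4} + n_{mal}\,\mathrm{C_3H_2O_3}.$$

Two biosynthetic facts restrict the space: every known rhamnose sits on a
glucose ($n_{dhex} \ge 1 \Rightarrow n_{hex} \ge 1$), and malonylation
esterifies a glucose C′-6 hydroxyl ($n_{mal} \le n_{hex}$). Positive-mode
electrospray produces `[M+H]+`, `[M+Na]+` and `[M+NH4]+` ions at

$$m/z = \frac{M + M_{adduct} - z\,m_e}{|z|},$$

with the electron mass $m_e = 0.00054858$ Da subtracted per positive charge.
At four-decimal accurate-mass precision this correction is not optional:
without it the computed lock-mass cation C12H19F12N3O6P3 would be 0.9 ppm
high. The package ships a fixed IUPAC/CODATA monoisotopic element table; it
is code, not configuration, because every downstream number depends on it.

All HGL-DTGs additionally shed an in-source fragment during ionization, the
aglycone stripped of both hydroxyls (cation C20H31+, *m/z* 271.2420). Its
EIC is a one-trace readout of the entire chemotype, and its presence among
MS/MS fragments "core-confirms" an annotation.

## Dereplication

`enumerate_compositions()` lists all constrained triples within bounds
(defaults hex ≤ 4, dhex ≤ 3, mal ≤ 4, chosen to cover every named compound
in the reference table, including dimalonylated nicotianosides);
`match_mz()` compares an observed m/z against every (composition, adduct)
ion. Numerical choices:

- **Tolerance.** Default 4 mDa absolute — the accurate-mass window used for
  formula determination on the targeted Q-TOF class — with an alternative
  ppm mode (mass error scales with m/z). Printed literature m/z values for
  this compound family deviate from theory by up to ~5 ppm, so matching is
  always tolerance-based; ties are broken by smaller |error|, then fewer
  total residues, then lexicographic composition, making results
  deterministic.
- **Classification.** A total partition: `aglycone` (no sugars),
  `intermediate` (exactly one sugar, or positional evidence of a free
  aglycone hydroxyl), `rhamnosylated` (any deoxyhexose), else
  `non-rhamnosylated`. The di-glucoside composition (2,0,0) is genuinely
  ambiguous — it is both lyciumoside I (complete) and a DTG 648-type
  intermediate; since only chromatography/MS2 can separate them, the package
  defaults to the complete compound and accepts an explicit
  `positional_evidence` flag. Isomer series collapse to one composition with
  names joined (`"G-3-HGL;G-17-HGL"`).
- **Fragment assignment.** Loss chains are searched over all multisets not
  exceeding the precursor composition (plus up to two waters, for the two
  aglycone hydroxyls), greedily longest-first in the fixed order
  hex > dhex > mal > water; the smallest-|error| chain wins. Explained
  fragments reconstruct the precursor m/z minus the summed losses exactly.
- **Reference names.** `inst/extdata/reference_compounds.csv` seeds named
  compounds. Compositions not stated outright in the primary literature
  (attenoside's sugar count, the nicotianoside malonyl series, the
  DTG-numbered intermediates inferred from nominal `[M+NH4]+` masses) are
  flagged `provisional` and the file is editable data, not asserted fact.
- The EIC target 329.2475 sometimes quoted for the intact aglycone matches
  neither the computed protonated nor sodiated species; the package exposes
  it only as the configurable literal `eic_target_aglycone`, never as a
  computed value.

## Chemotyping

`compute_eic()` takes the per-scan **maximum** intensity within ±0.01 Th
(default) — the robust choice for centroided data, where split centroids
would double-count under summation. `integrate_peak()` is plain trapezoidal
integration with no baseline subtraction by default (vendor integration
settings are generally unstated; an optional linear baseline is provided).
Window endpoints are interpolated so adjacent windows tile additively.

`fold_change_matrix()` reports $\log_2((a + \varepsilon)/(\bar a_{ctrl} +
\varepsilon))$ with pseudo-count $\varepsilon = 1$ intensity unit: a
knockout's absent compound shows a large finite negative value rather than
$-\infty$, and an everywhere-absent compound an exact zero row. The log2
scale itself is a package choice (heatmap conventions vary); it is symmetric
in up/down regulation and is documented rather than silently assumed.
`quantify_by_internal_standard()` implements single-point internal-standard
quantification (`area ratio × spiked nmol / g FW`), with a zero standard
area treated as a failed spike (error), not as zero concentration.

## Candidate discovery

`pspg_model()` builds a position weight matrix over the ~44-residue PSPG box
from a packaged **synthetic** seed alignment
(`inst/extdata/pspg_seed_synthetic.fasta`), written as conservative variants
around the canonical family consensus; scores are summed log2 odds against a
uniform background, with `X` contributing 0 bits. The score threshold
(8 bits) was frozen from the empirical null of best-window scores over
random-composition proteins — 99.9% quantile ≈ 6.5 bits at typical UGT
lengths, rounded up for margin — while genuine boxes score above 15 bits.
"At the C-terminus" is operationalized as the hit starting within the last
40% of the sequence (`cterm_fraction = 0.4`), a documented heuristic.

Co-expression uses the plain Pearson coefficient on `log2(x + 1)` (the
microarray convention; switchable), with zero-variance vectors reported as
missing rather than silently dropped. `rank_candidates()` applies three
filters — PCC ≥ 0.6 to *every* bait, shoot/root fold ≥ 10, induction fold
≥ 3 at the 5-h time point — and ranks survivors by mean bait PCC with a
lexicographic tie-break. The thresholds sit just below the weakest values
printed for any experimentally confirmed candidate in this pathway (bait
PCC 0.608, root fold 20, induction 6-fold), so all confirmed candidates
pass with margin while near-uncorrelated background does not. Fold
computations use pseudo-count 1.0. `tissue_specificity()` accepts a
`treatment` restriction because leaf-side induction otherwise inflates the
leaf/root ratio above the constitutive suppression factor one wants to
estimate.

## What the generators emulate — and what they do not

`gen_peaklists()` plants each compound as a Gaussian elution profile at each
adduct m/z, splitting abundance deterministically across the adduct mixture
(default 20/50/30% H+/Na+/NH4+), with one Normal(0, 2 ppm) mass-error draw
per ion (a calibration-offset model), a co-emitted core fragment at 20% of
the summed DTG signal, and uniform-m/z, exponential-intensity noise. Gaussian
shapes were chosen because their closed-form area ($A\sigma\sqrt{2\pi}$)
independently checks the integrator. `gen_knockout_profile()` rewrites the
panel with documented multipliers: rhamnosylation knockout ×0.01 on
deoxyhexose compounds and ×2 on the rest (the chemotype *shift* seen when
rhamnosylation is silenced), glucosylation knockout adds the free aglycone
and one/two-sugar intermediates, precursor knockout scales everything ×0.1.

`gen_expression()` emulates a 3 tissue × 6 time (1–21 h) × 3 treatment
herbivory-induction compendium at 3 replicates per stratum (162 columns,
standing in for the ~150-profile design; the per-stratum replication of the
original is not public). Module genes share one log2-scale mean structure —
induction peaking 8-fold at 5 h under simulated herbivory, half-exponent
under wounding, none in roots — times gene-specific baselines and 20–3000×
root suppression, plus independent Normal(0, 0.5) log2 noise; background
genes are i.i.d. lognormal. Known pathway genes carry their published root
suppression folds (50, 3225, 2190, 127, 20).

Not emulated, deliberately: isotope envelopes, chimeric spectra,
retention-time drift between samples, probe-level microarray artifacts,
normalization batch structure, and correlated background modules. Passing
tests therefore demonstrate that the *algorithms* recover planted structure
under the stated noise model — not that the defaults are optimal for any
particular instrument, and a real compendium's correlated background would
make the PCC filter less specific than the simulation suggests.

## Problem sizes and determinism

Every generator is a pure function of (config, seed), and pipeline runs log
the seed and a config hash. The test suite uses sizes chosen to keep the
full run around a minute while leaving the statistical checks
well-powered: exhaustive enumeration cross-checks up to bounds (6,6,6);
annotation round-trips over 50 seeds at 5 ppm error / 15 ppm tolerance;
candidate-ranking sensitivity over 200 replicates of the 109-gene × 162-
sample compendium; 1000-shuffle motif nulls. Degenerate inputs (empty peak
lists, zero-variance expression, zero internal-standard area, empty
integration windows, impossible thresholds) are exercised explicitly and
either return well-defined empties or error with a named cause.

## Known limitations

- Composition-level annotation cannot resolve positional isomers or
  distinguish lyciumoside I from two-sugar intermediates without external
  evidence; both facts are surfaced in the API rather than hidden.
- Negative-mode ionization, multiply charged species and isotope-pattern
  scoring are out of scope.
- The PSPG seed alignment is synthetic; for production scans it should be
  replaced (via `pspg_model(alignment = ...)`) with a curated alignment of
  experimentally annotated UGT C-termini.
- Single-point internal-standard quantification assumes equal response
  factors; calibration curves are intentionally not implemented.
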