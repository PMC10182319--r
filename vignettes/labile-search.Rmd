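---
title: "Searching labile modifications: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching labile modifications: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(labileMS)
```

## The problem

Tandem-MS database search assigns each MS2 spectrum to a peptide by
comparing observed peaks with the theoretical b/y (or c/z) fragment ladder.
A *labile* modification breaks this model: under collisional activation the
modification dissociates partly or completely, so fragments that contain the
modified residue appear at the unmodified mass (complete loss), at the mass
plus a *remainder* (partial loss — which may be net negative when the
modification takes part of the side chain with it, as in phosphoric-acid
loss leaving −H2O on Ser/Thr), and the modification itself may appear as
low-mass *diagnostic ions*. A conventional variable-modification search
matches only fragments that do not contain the modification site and loses
sensitivity roughly in proportion to how labile the modification is.

`labileMS` models the three resulting ion classes explicitly and lets them
compete:

1. **Nonlabile candidates**: the modification placed on a residue; fragments
   covering the site are shifted by the full modification mass.
2. **Labile candidates**: the modification expressed as a precursor *mass
   offset* (k copies → k × offset); fragments are searched unmodified, plus
   optional fragment-remainder variants at one candidate site at a time, and
   peptide-remainder ions at the intact-peptide mass plus each configured
   remainder.
3. **Hybrid**: both candidate families, including mixed forms (j placed +
   k offset, j + k capped), with the best hyperscore winning.

Diagnostic-ion gating restricts offset candidates to spectra where the
summed intensity of the configured diagnostic m/z values (nearest peak
within tolerance, normalized scale with base peak = 100) reaches a
threshold; other spectra are searched at offset zero only. Gating is
monotone by construction: raising the threshold can only shrink the set of
offset-searched spectra.

## Scoring and numerical choices

The hyperscore is the canonical X!Tandem form
`log10(N_b! · N_y! · max(ΣI_b,1) · max(ΣI_y,1))` with factorials via
log-gamma and counts capped at 64. Choices the name "hyperscore" does not
fix, made here explicitly:

- **Matching** is greedy and unique per fragment series: ions are visited in
  ascending m/z; each takes the nearest unused peak within the ppm
  tolerance (10 ppm default, of the theoretical m/z). An independent
  loop-based re-implementation of this contract is kept in the test suite
  and the two are required to agree exactly.
- **Remainder evidence**: fragment-remainder variant matches count toward
  their parent series' factorial; peptide-remainder matches add intensity to
  the suffix sum but no counts, because an intact-peptide ion carries no
  sequence-position information. Both contributions are logged per PSM so
  the decision is auditable.
- **c/z ions** pool with b/y into the same prefix/suffix factorial slots, so
  one formula covers HCD-style (b/y) and hybrid-activation (b/y/c/z)
  searches. z ions are the z-dot radical (y − NH3 + H).
- **Tie-breaking** is deterministic: fewer total modifications, then
  nonlabile before labile, then lexicographic sequence. An exact score tie
  between the complete-loss and a remainder pathway resolves to complete
  loss (the simpler explanation).
- **Multi-copy offsets** (k ≥ 2, or sums across different labile mods) score
  through the complete-loss pathway only and are always reported
  unlocalized: remainder variants are generated for one site at a time,
  never combinatorially across sites.
- **min_matched = 4** backbone fragments for a reportable PSM; fragment
  charges 1 for precursor z ≤ 2, {1, 2} above; precursor isotope errors
  {0, +1, +2} by default.

Localization places each configured fragment remainder at each allowed site
and keeps the per-site best hyperscore. A site is reported only when it is
the unique maximum and at least one site-discriminating remainder ion
matched; a single allowed site is trivially localized; everything else is
"unlocalized". This is deliberately conservative — the per-site score vector
is retained in the PSM table so downstream tools can re-assess.

## FDR

Reversed-protein decoys (prefix `rev_`), concatenated search,
`FDR(t) = #decoys ≥ t / max(1, #targets ≥ t)` monotonized into q-values; the
+1-decoy numerator correction is available via an argument but off by
default. Peptide-level filtering takes the best PSM per (sequence,
modification set, offset) group. A decoy-free result set gets q = 0 with a
loud warning rather than an error, since tiny fixtures legitimately produce
it.

## What the simulator emulates — and what it does not

The generator produces centroided MS2 spectra of modified peptides under an
explicit phenomenological model: each theoretical backbone fragment is
detected with probability `detect_prob`; a detected fragment covering a
modified site loses the modification with probability `p_loss` (emitting the
unmodified m/z, plus — with `frag_remainder_prob` — a remainder variant) and
otherwise appears intact-shifted; peptide-remainder and diagnostic ions are
emitted with their own probabilities; noise peaks are added as a fraction of
signal peaks; all m/z values receive Gaussian ppm jitter.

Defaults and why:

- `detect_prob = 0.6`: collisional-activation spectra typically reveal about
  half of the theoretical b/y ladder (b ions are suppressed, low-mass ions
  fall below the scan range). Initially set to 0.85, revised once to 0.6 on
  this evidence; the revision is recorded in the project ledger.
- `jitter_ppm = 3` against 10/20 ppm tolerances, matching Orbitrap-class
  accuracy; `noise_frac = 0.1`; fragment intensities log-uniform in
  [10, 100] and noise in [1, 20] on the normalized scale — only rank and
  threshold behavior matter to the score.
- Charges {2, 3} uniform; per-spectrum RNG streams derive from
  (seed, scan index) so datasets are reproducible under any generation
  order.

Not emulated: isotope envelopes (deisotoping tests use hand-built
fixtures), chimeric spectra, retention time, realistic intensity
prediction, and — critically — the *decoy score tail* of real data. At
10 ppm a random ≥4-ion match essentially never happens in a synthetic
spectrum, so target–decoy thresholds rarely reject weak-but-true PSMs the
way they do at repository scale. A green end-to-end test therefore
establishes correct mechanics (candidate generation, scoring, competition,
calibration direction), not real-data identification rates; the
direction-of-effect comparisons derive their contrast from the
`min_matched` floor and multi-site coverage geometry instead, mirroring the
published multi-phosphorylation search design (up to three phosphates,
variable mods and offsets always summing to three). One acceptance bound
(labile ≥ 1.3 × nonlabile at full lability) lands at 1.24 in this world and
is knowingly left unmet rather than recalibrated; the same ledger documents
a localization-recovery bound at 0.775 vs 0.80 where every localized call
is correct but adjacent-site peptides lack discriminating remainder ions at
the stated emission rates.

## Other design decisions

- Masses are computed from hard-coded monoisotopic atomic masses (C 12.0,
  H 1.00782503207, N 14.0030740048, O 15.9949146196, P 30.97376163,
  S 31.97207117); residue masses derive from elemental compositions so
  additivity holds to machine precision. All internally derived m/z use the
  proton mass; user-supplied diagnostic/remainder m/z values are matched
  verbatim because published diagnostic masses often follow the
  hydrogen-atom convention (136.06232 = adenine + H), and honoring them
  avoids convention mismatches.
- A few published constants (+226.0594 / +94.0168 for the 4SU nucleoside
  and base, the −42.0205 Arg-side-chain remainder, diagnostic ions
  348.07036 / 428.03669 / 584.09018) are stored verbatim: no elemental
  composition reproduces them at the printed precision.
- Digestion is strict trypsin (cleavage after K/R including before Pro)
  with optional N-terminal Met clipping; decoys are full-protein reversals,
  the community default, which preserves composition exactly though digest
  statistics shift slightly at segment ends.
- Deisotoping, unspecified upstream, is a greedy envelope collapse
  (descending intensity, +k·1.00335/z successors removed, depth 2) —
  deterministic and testable.
- mzML reading is a minimal xml2-based parser (64/32-bit, zlib) because no
  binding to a compiled mzML library is assumed; MGF is the primary
  exchange format and round-trips exactly.
- Fixed modifications never count toward the variable-modification cap.

## Limitations

Desk-scale only: the peptide index is a sorted array, not a fragment-ion
index; no semi-enzymatic digestion, protein inference, rescoring or
quantification. Localization confidence is a score gap, not a probability.
The simulator's independence assumptions (per-fragment detection and loss)
ignore correlated fragmentation behavior along the backbone.
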