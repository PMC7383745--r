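---
title: "Glyco-group fingerprinting of Chlorella N-glycans: models and methods"
author: "glycofinger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glyco-group fingerprinting of Chlorella N-glycans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycofinger)
```

## The problem

Chlorella-like microalgae attach an unusually diverse set of N-glycans to
their proteins: varying numbers of hexoses, N-acetylhexosamines (HexNAc),
pentoses (arabinose, xylose), deoxyhexoses (fucose), and O-methyl groups.
MALDI-TOF spectra of the released, underivatized, reducing glycans —
measured as singly charged sodium adducts — resolve into a small number of
recurring fingerprint patterns, thirteen of which are named glyco-groups
(Kei, Hel, Jos, Ori, Raa, Now, Sun, Sol, Jar, Gov, Ama, Asp, Pit). This
package implements the calculus that underlies reading such spectra: exact
composition mass arithmetic, peak-to-composition assignment, MS/MS-based
inference of chitobiose-core substitution, rule-based group classification,
and a concordance statistic against a DNA phylogeny.

## Mass arithmetic

A glycan composition is a count vector over \{Hex, HexNAc, Pen, Me, dHex\}.
Residue monoisotopic masses are fixed at five decimal places (Hex 162.05282,
HexNAc 203.07937, Pen 132.04226, Me 14.01565, dHex 146.05791; water
18.01056; sodium cation 22.98922, electron-corrected; proton 1.00728).
The neutral mass of a reducing glycan is the residue sum plus one water;
the MALDI default ion is `[M+Na]+`. Since a deoxyhexose and a methylated
pentose share the elemental formula C6H10O4, `dhex = pen + me` holds
exactly, and MS1 compositions are reported in the folded (Pen+Me) canonical
form — which residue actually carries a methyl, or whether a Pen+Me pair is
really a fucose, is a structure-level question MS1 cannot answer.

The "os" shorthand writes the folded counts in the order Hex, HexNAc, Pen,
Me, bracketing counts of ten or more: `os3231` is Hex3HexNAc2Pen3Me1
(m/z 1343.46), `os[10]213` is Hex10HexNAc2Pen1Me3 (m/z 2241.8). This
constant set reproduces every printed reference mass at its printed
precision; reported values are rounded half away from zero, matching the
printed tables. Two printed values do not fit the arithmetic and are
deliberately not used as anchors anywhere: 2565.7 for `os[12]213`
(computed 2565.92) and the doubly charged 736.2 attributed to `os3230`.

## Peak annotation

`decompose_mass()` enumerates all compositions within a bound box
(Hex 0–12, HexNAc 2–4, Pen 0–4, Me 0–8 by default — covering every
composition the thirteen groups use) whose sodiated m/z falls within a
tolerance of the query. The default MS1 tolerance is 0.15 Da after internal
recalibration, reflecting reflectron-MALDI accuracy and the 0.1-Da
agreement of the printed values; the pre-calibration anchor search window
is 0.5 Da. Ties are broken deterministically by absolute error, then total
residue count, then lexicographically. No matching tolerance or intensity
floor is stated in the source material; these defaults are engineering
choices and are exposed as arguments.

`recalibrate()` uses the oligomannosidic glycans Man5–Man9 (Hex5..9HexNAc2,
present in virtually every sample) as internal calibrants, fitting
`true = offset + slope * observed` by least squares on the matched anchors.
Because the affine family contains the identity, the fit can never increase
the anchors' residual sum of squares; with fewer than two matched anchors
the spectrum is returned unchanged with a warning.

`annotate_spectrum()` assigns every peak above an intensity floor (default
1 % of the base peak) and flags oligomannosidic assignments.
`detect_methyl_ladder()` groups assignments differing only and
consecutively in Me — the 14-Da ladders characteristic of O-methylation —
and reports the per-spectrum maximum methyl count on oligomannosidic
glycans, which separates lightly methylated groups (Gov, up to three) from
heavily methylated ones (Ama, up to seven).

## Fragment inference

For MS/MS (LIFT) spectra, `enumerate_fragments()` lists every bipartition
of the precursor composition as a complementary b/y pair (y retains the
reducing end and its water; both carry the sodium; `m(b) + m(y) =
precursor + Na` exactly) plus the canonical neutral-loss ladder: loss of
the reducing GlcNAc (221.09 Da), of both core GlcNAcs (221.09 + 203.08), of
a methylated second GlcNAc (221.09 + 217.09), and the deoxyhexose cascade
(146.06, then 221.09). Internal (by) ions are isobaric with b ions of the
same retained composition at this level and are not listed separately.
The default MS2 tolerance is 0.3 Da, the deviation LIFT masses show from
theory.

`infer_core()` applies four reading rules in fixed order:

1. a direct 221.09 loss means GlcNAc-1 is unsubstituted;
2. consecutive 221.09 and 203.08 (or 217.09) losses mean the whole
   chitobiose is unsubstituted (the 217.09 variant sets a
   methylated-HexNAc flag);
3. if no fragment lacking both core GlcNAcs is observed but a
   complementary b/y pair splitting exactly at the chitobiose is, the
   second GlcNAc carries the substituent — operationalized as: no matched
   `-2 Gn`/`-2 Gn(Me)` ion, and a matched pair whose y member retains
   exactly HexNAc2 plus at least one further residue;
4. if the 221.09 loss occurs only after a 146.06 loss, GlcNAc-1 carries
   core 1,3-linked fucose; this is checked before GlcNAc-1 is declared
   unknown.

Evidence accumulates monotonically; a direct 221.09 loss co-occurring with
the fucose cascade raises an inconsistency flag rather than silently
resolving. Logical closure (an unsubstituted chitobiose implies both
GlcNAcs free; core fucose implies a substituted GlcNAc-1) is applied by the
`core_evidence()` constructor, which rejects contradictions.
`pngase_release()` translates core fucose into enzyme behaviour: PNGase F
does not cleave glycans with core 1,3-fucose, PNGase A does — so
isobaric 1211.4 glycans can share a mass yet separate by release class.

One printed fragment value, a "211.1" loss for a free reducing GlcNAc, is
treated as the 221.09 rule (a suspected transcription slip; 221.09 is the
only loss consistent with the residue masses).

## Classification

Each group profile (packaged as versioned, editable YAML) lists required,
supporting, and forbidden diagnostic masses with their os codes, an
optional allowed range for the oligomannose methylation maximum, and a
ladder rule. Scoring: required diagnostics weigh 2, supporting diagnostics
and the methylation predicate weigh 1; the score is the matched fraction of
total weight. "Dominant" required peaks must reach 25 % of the base peak,
presence means the 1 % floor; the dominance figure is a design choice made
so that published-pattern-like spectra classify cleanly, as no quantitative
definition of "dominant" exists in the source data. A forbidden diagnostic
above the dominance threshold zeroes the profile. Required and supporting
matching goes through composition assignments (so it inherits the 0.15-Da
tolerance); forbidden matching uses raw peak m/z with a wider 0.4-Da
window, because zeroing guards against a gross pattern mismatch and should
not hinge on a borderline assignment.

The best group must score at least 0.5, otherwise the spectrum is an
orphan — with the weights above, a spectrum of bare oligomannose anchors
scores below 0.5 everywhere and abstains. A second-best score of 0.35
raises the mixture flag; commercial products are frequently strain
mixtures, so flagging rather than silently misclassifying is the intended
behaviour, and the flag fires routinely for the MS1-confusable sibling
groups. The tentative 'Wel' subtype of Jos remains profile metadata, and
the heterogeneity of 'Ori' is handled by the mixture flag, keeping the
registry at exactly 13 groups.

`confusability_report()` documents which pairs MS1 cannot separate without
series rules: identical required sets (Raa/Now, Gov/Ama — methylation
only), single-mass differences (Sol/Jar via 1460.5; Jar/Gov, Jar/Ama via
1197.4), and nesting of one group's required set inside another's
diagnostics where no dominant forbidden mass intervenes (Sol/Gov, Sol/Ama,
Kei/Asp).

## The synthetic-spectrum generator

`simulate_ms1()` emulates the published fingerprints: group diagnostics at
rank-based template intensities (dominant 100, supporting 30, anchors 15,
ladders decaying by 0.6 per methyl step), Man5–Man9 anchors with
group-specific methylation ladders, log-normal intensity dispersion
(sigma 0.3), per-peak Gaussian ppm mass error followed by a linear
calibration drift, Poisson-distributed decoy peaks drawn uniformly in
900–2600 Da but at least 1 Da from any theoretical glycan mass, and
optional contamination by a second group. One RNG stream is derived per
spectrum from (seed, index) so that subsets reproduce. The default mass
error of 50 ppm (roughly 0.07 Da at m/z 1400) deliberately stresses the
fixed 0.15-Da matching tolerance.

What it does *not* emulate: profile (continuous) peak shapes, isotope
envelopes, detector saturation, chemical background, and real intensity
ratios — so passing benchmarks demonstrate the correctness of the
arithmetic and decision rules under the stated error model, not
instrument-level performance on real spectra.

`simulate_ms2()` emits exactly the fragment set consistent with a declared
core-substitution truth (suppressing the direct 221.09 loss for
core-fucosylated truth, and so on), so that at zero noise
`infer_core(match_lift(simulate_ms2(x)))` returns `x` for all four
archetypes. `simulate_labeled_tree()` builds a backbone tree with groups as
monophyletic clades and then reassigns each leaf's label with a given
mixing probability.

## Concordance with a phylogeny

`group_monophyly()` restates "the rDNA tree reflects the glycan grouping"
as a statistic: the fraction of glyco-groups whose labelled leaves are
monophyletic, ignoring unlabelled leaves (outgroups, reference
accessions). Non-monophyletic groups are split into paraphyletic (the
complement of the group is monophyletic) and polyphyletic. Unrooted input
is midpoint-rooted, mirroring the published tree's rooting; bootstrap
values as node labels parse and are ignored. Trees are consumed, never
inferred — alignment and tree building are standard off-the-shelf steps
outside this package's scope. Because the source reports concordance only
qualitatively, the property asserted (and tested) is monotone decline of
mean concordance with label mixing, not a numeric target.

## Benchmark sizes and numerical choices

The packaged test suite runs the classifier benchmark at 50 spectra per
group and 50 ppm mass noise (650 spectra, about half a minute), the
decomposition oracle comparison at 50 random masses across 900–2600 Da,
and the concordance property at 100 trees for each of four mixing rates —
sizes chosen to make the statistics stable while keeping a full check
quick on a laptop. Typical benchmark behaviour: about 97–98 % best-group
accuracy, with wrong-group errors confined to the documented
MS1-confusable pairs and the remaining errors being orphan abstentions of
single-required-mass groups whose marker peak drew a > 2-sigma mass error
(at 50 ppm, 2–3 % per group); between-group separation is protected by the
raw-m/z forbidden checks, abstention is not, by design.

Other numerical conventions: reported m/z rounds half away from zero (1 dp
by default, 2 dp where printed so); empty decomposition results are valid
outcomes, not errors; the HexNAc >= 2 N-glycan validity check is enforced
by fragment enumeration but not by generic mass arithmetic; degenerate
inputs (empty spectra, single-anchor calibration, single-leaf groups)
return well-defined results rather than failing.

## Known limitations

* MS1 cannot distinguish a deoxyhexose from pentose-plus-methyl, nor say
  which residue is methylated; the package reports folded compositions and
  flags dHex aliases instead of guessing.
* Fragment inference is composition-level; linkage and topology are out of
  scope (NMR territory).
* The registry's supporting-mass sets carry only masses actually printed
  for each group and are marked extensible; richer profiles would sharpen
  classification of the rarer groups.
* Intensity information is used only ordinally (dominance vs presence);
  no intensity-profile learning is attempted.
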