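---
title: "Identifying polyester oligomer migrants from mass spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying polyester oligomer migrants from mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyestermz)
library(dplyr)
```

## The problem

Polyester can coatings are condensation polymers of polyvalent carboxylic
acids (phthalic-type isomers PA/IPA/TPA, adipic acid, trimellitic acid)
with polyols (neopentyl glycol, ethylene glycol, butanediols, CHDM, ...).
The polymerisation leaves behind short oligomers — non-intentionally added
substances — that can migrate into food. They have no commercial
standards, no toxicological data and no specific migration limits, so
identification rests on mass spectrometry plus combinatorial reasoning:
every plausible oligomer is generated in silico from a monomer library,
and observed MALDI-TOF or LC-MS<sup>n</sup> peaks are matched against the
resulting ion table. `polyestermz` implements that workflow end to end.

## The model

### Oligomers as compositions

An oligomer is modelled as a multiset of monomer units plus a topology.
Positional isomers and isobaric monomer isomers (PA/IPA/TPA;
1,3-/1,4-butanediol and 2-methyl-1,3-propanediol) are deliberately *not*
distinguished: they co-elute or share exact mass, and the field reports
them jointly. Each ester bond condenses out one water, so for a
composition with $u$ units,

$$ M_\mathrm{linear} = \sum_i m_i - (u-1)\,m_{\mathrm{H_2O}}, \qquad
   M_\mathrm{cyclic} = \sum_i m_i - u\,m_{\mathrm{H_2O}}, $$

with $m_{\mathrm{H_2O}} = 18.010565$ Da and all $m_i$ monoisotopic.
Average masses are never used; every reproduced literature m/z follows
from monoisotopic arithmetic.

### Feasibility rules

Ester chemistry imposes alternation of acid and alcohol functions:

* **cyclic**: all units difunctional (diacid, diol, or hydroxyacid) and
  the diacid count equals the diol count; ring-opened caprolactone can
  close a ring on its own, in any number.
* **linear**: the polyacid and polyol unit counts differ by at most one
  (admitting both diacid-terminated and diol-terminated chains);
  hydroxyacids insert anywhere; monools cap chain ends (at most two,
  only on acid-bearing chains; off by default).
* **tri-functional units** (trimellitic acid, glycerol,
  trimethylolpropane) force linear (tree) topology. The published
  feasibility reasoning fixes only the diacid/diol case; counting all
  polyacids against all polyols, with branch points excluded from rings,
  is this package's generalisation — branched rings are combinatorially
  under-determined and are deliberately not enumerated.

Enumeration defaults mirror the screening conventions: at most 8 units
(homologous series are reported up to n = 8) and a 1000 Da neutral-mass
cutoff, because heavier species are not absorbed in the gastrointestinal
tract and are toxicologically disregarded. Correctness of the generator
is checked against a brute-force oracle (all count vectors, feasibility
applied post hoc) on small libraries.

### Ionisation

All observable species are singly charged. Adduct m/z values are the
neutral mass plus a fixed ion-mass delta (+1.007276 H, +18.033823 NH4,
+22.989218 Na, +38.963158 K, −1.007276 for [M−H]⁻). MALDI spectra with a
sodium-salt cationization agent are Na-dominant; LC-ESI spectra mix
H/NH4/Na/K. The targeted negative-mode screen reports exact [M−H]⁻
masses for the free acid monomers; published unit-resolution window
centres that sit ~0.2 Da off exact masses are treated as instrument
calibration offsets, not as ground truth.

### Matching and tolerances

The matching tolerance is instrument-specific and configurable, because
the underlying studies do not state one: 10 ppm for reflector MALDI-TOF
(the quoted external-calibration accuracy) and 0.3 Da for a
unit-resolution ion trap. Every candidate within tolerance is reported —
isobaric ambiguity is information — with rank 1 marking the smallest
absolute error; ties break toward fewer distinct monomer types, then
fewer units, then the canonical composition string. Reported error is
observed minus theoretical, sign preserved. When comparing computed m/z
with printed one-decimal tables, rounding is half away from zero
(`round_half_away()`); several published ion-trap values sit 0.2–0.5 Da
above monoisotopic arithmetic and can only be matched in Da-tolerance
mode, never exactly.

### Homologous series and monomer inference

A repeat unit is one diacid+diol residue pair (−2 H₂O; e.g. PA+NPG =
234.089 Da) or one hydroxyacid residue (−1 H₂O; caprolactone =
114.068 Da). Series detection is greedy nearest-peak chaining: start at
any peak with no predecessor one unit below, repeatedly take the nearest
peak to (current + unit) within tolerance (default 0.2 Da for reflector
MALDI), and keep maximal chains of at least 3 members. Greedy chaining
mirrors how an analyst reads a polymer spectrum; on very dense spectra it
can absorb coincidental peaks, which is why inference (below) weighs
series by explained intensity rather than by member count. Monomer
exchange shows up as fixed mass offsets between adjacent series (NPG→HD
+14.016, NPG→CHDM +40.031, NPG→EG −42.047 Da), counted over all peak
pairs.

`infer_monomer_set()` combines both: for each acid isobaric group, the
candidate subset collects the diols whose repeat units support series,
ranked by the summed intensity of the members they explain — an ordinal
proportion statement only, no quantification claim. Two thresholds
matter: series need `min_length = 3` members, and a diol is kept only if
it explains at least `min_intensity_fraction = 0.01` of the strongest
diol's intensity. The floor exists because a multi-adduct spectrum
contains arithmetically systematic spacings (adduct-mass differences
combined with water and residue masses) that produce weak coincidental
chains; one percent of the dominant signal separates those cleanly from
real minor co-monomers in all synthetic conditions exercised here.

### Fragmentation

Product-ion candidates for a protonated precursor are generated by
composition arithmetic, not bond-resolved mechanisms: every non-empty
sub-multiset of the parent, with water-equivalent losses from (units−1)
to (units+1) capped by the elemental formula, plus the precursor −
k·H₂O ladder (k = 1, 2) for the full composition. This heuristic
reproduces every interpreted ester-cleavage fragment in the reproduction
suite (m/z 149, 193, 235, 359, 383, 415, ...). One literature
interpretation — m/z 383 read as "2 NPG + PA, protonated" — computes to
339.18; the arithmetic-consistent assignment is 2PA+NPG with three water
equivalents lost (383.11), and that is what the package reports. Sodiated
and ammoniated precursors return no candidates, mirroring the
experimental observation that they do not fragment usefully.

### Safety screening

The Cramer/TTC module implements only the published summary rule: cyclic
oligomers containing an aromatic dicarboxylic acid are class III
(1.5 µg/kg bw/day exposure threshold); linear oligomers are class I
(30 µg/kg bw/day); anything else — e.g. caprolactone rings or aliphatic
cyclic esters — is `unresolved` and flagged for evaluation with the full
33-question decision tree, never guessed. Linear oligomers are only
*mainly* class I in the literature, so class I rows are a screening
verdict, not a toxicological assessment. The class II threshold
(9 µg/kg bw/day) ships as a constant but is never assigned by the rule.

## The synthetic-data generator

`simulate_maldi_peaklist()` exists so the whole pipeline is testable
without instruments. It emulates:

* all feasible oligomers of a declared formulation within a unit range
  (default 2–8), with expected intensity proportional to the product of
  the monomer proportions, weighted 0.8 cyclic / 0.2 linear (most
  migrating oligomers are ring-closed because they lack free functional
  groups);
* every adduct form of each neutral at fixed abundance ratios
  (Na-dominant by default, as with NaTFA cationization) — adduct forms
  co-occur in a real spectrum, they are not sampled one per molecule;
* a detector dynamic-range floor (default 10⁻³ of the strongest
  observable peak, applied after clipping to the m/z 350–4000 window);
* Gaussian m/z error with σ = accuracy/3 — a stated "10 ppm accuracy"
  is read as a ±3σ window — log-normal intensity jitter (σ_log 0.3),
  and uniform-m/z chemical noise with exponentially distributed
  intensities.

The two reference formulations mirror the spectral patterns the package
is designed around: `formulation_cm1()` (PA with NPG/HD/BD plus a
caprolactone series; ±14 Da exchange groups) and `formulation_cm2()`
(PA with NPG/CHDM/EG; +40/−42 Da exchange groups). The intensity and
noise laws are inventions — no intensity model is published — so passing
tests demonstrate correct arithmetic, ranking and robustness of the
algorithms, not instrument realism: isotope envelopes, detector
saturation, matrix clusters and chromatographic effects are all absent,
and real spectra will be harder.

All randomness flows from one mandatory seed through `withr::with_seed()`;
there is no hidden global state.

## Problem sizes and numerical choices

The shipped 17-monomer library yields roughly 2.4 × 10⁵ feasible
compositions at the 8-unit / 1000 Da defaults (a few seconds to build);
the test suite exercises the statistical guarantees at smaller scales
chosen for tight feedback: brute-force oracle comparisons on 2–3 monomer
libraries at ≤ 5 units, series robustness over 100 seeded progressions,
end-to-end annotation and monomer inference over 50 seeded synthetic
spectra each. Mass comparisons use 10⁻⁹ Da for additivity identities,
10⁻⁴ Da against derived reference values, and the instrument tolerances
above against printed ones. Degenerate inputs (empty libraries, empty
peak lists, all-noise spectra, unsorted input) return empty results or
sort with a warning rather than failing.

## Known limitations

* Compositions, not structures: sequence isomers, stereochemistry and
  branch positions are outside the model.
* Greedy series chaining is not a global optimisation; dense spectra can
  fragment a true series around a missing member.
* The default monomer library approximates the industrial formulary
  (the full proprietary list of 19 polyols / 6 polyacids is not public);
  it is user-extensible via CSV config.
* The Cramer rule is a two-branch heuristic consistent with the
  reproduced classification table; it is not Toxtree.
* Charge is limited to ±1 and isotope patterns are not simulated.
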