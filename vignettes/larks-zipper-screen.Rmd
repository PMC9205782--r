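---
title: "Screening missense mutations that convert kinked amyloid segments into steric zippers"
author: "larkscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening missense mutations that convert kinked amyloid segments into steric zippers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Low-complexity domains (LCDs) of proteins such as FUS, hnRNPA1/A2, TDP-43
and keratin-8 (KRT8) self-assemble reversibly through LARKS —
low-complexity amyloid-like kinked segments.  A LARKS forms stacked
beta-sheets whose strands carry a kink (typically at a glycine), which
limits how tightly two mated sheets can adhere; the assembly remains
labile.  Pathogenic amyloid, by contrast, is built of steric zippers: two
pleated beta-sheets whose side chains interdigitate.  A missense mutation
inside a LARKS can convert the kinked motif into a zipper-competent
pleated segment and thereby turn reversible assembly into irreversible
aggregation.  KRT8 is the motivating case: the head-domain variants Y54H,
G55A and G62C all lie in LARKS of the glycine-rich head domain, and
crystal structures of the wild-type and mutant segments show the
conversion directly — wild-type SGMGGIT (residues 58–64) is an
antiparallel class-7 zipper with the two central glycines in a highly
extended (near-|180°| phi/psi) conformation, while the G62C mutant
SGMGCIT forms a parallel class-2 zipper with Cys62 pleated, and the G55A
mutant GGYAGAS an antiparallel class-6 zipper.

`larkscreen` implements the computational half of that analysis:

1. **LARKS detection** — fixed-backbone threading of every hexapeptide
   window of a protein onto three kinked backbone templates.
2. **Variant mapping** — intersection of a missense-variant table with the
   accepted LARKS windows.
3. **Zipper conversion scoring** — threading of the wild-type and mutant
   windows onto a pleated steric-zipper template; the energy difference
   `delta = E_zip(mut) − E_zip(wt)` and an absolute-score gate call the
   conversion.
4. **Fibril-structure geometry** — strand/sheet detection, steric-zipper
   class assignment (classes 1–8), pleated/extended/kinked backbone
   labels, and buried interface area.

## The threading model

A `BackboneTemplate` is a per-residue (phi, psi, omega) table realized as
ideal-geometry backbone coordinates and expanded into a fibril context:
two sheets of five strands, the query threaded onto every strand
(homotypic, in-register — amyloid fibrils are stacks of identical
layers).  Side chains are placed by a coarse, backbone-independent
rotamer library (chi grid at ±60°/180°, at most 9 rotamers per residue)
and optimized by symmetry-coupled iterative best-rotamer sweeps: all
strand copies share one rotamer per position, sweeps continue until no
single-position change lowers the energy, ties resolve to the lowest
library index, so packing is deterministic.

The energy is an original four-term function in arbitrary units — it
makes no attempt to reproduce any published force field's magnitudes,
because only orderings and thresholded calls are consumed downstream:

* `E_rep` — soft steric overlap on inter-residue atom pairs (plus a fixed
  backbone-strain penalty for proline threaded at positions whose
  template phi lies outside −100..−30°);
* `E_att` — a capped attractive well rewarding packing contacts;
* `E_solv` — pairwise desolvation: burying apolar atoms is mildly
  rewarded, burying polar atoms penalized, with strong penalties for
  charged groups (carboxylates, lysine/arginine nitrogens);
* `E_hb` — a geometric hydrogen-bond reward (heavy-atom donor–acceptor
  distance 2.6–3.5 Å, parent–acceptor–donor angle ≥ 90°).

`E_total = w_rep·E_rep + w_att·E_att + w_solv·E_solv + w_hb·E_hb` holds
exactly.  The shipped weights (3, 0.2, 0.5, 1.5) were fixed by the
calibration procedure below; the dominant repulsion weight is what makes
the score a *fit* measure (can this sequence adopt this backbone?) rather
than a contact count that would trivially favour large residues.

## Templates

The three kinked templates are named for the segments whose fibril
structures motivated them (STGGYS, SYSGYS, GYNGFG).  Their published
coordinates are not redistributed; the tables shipped here are idealized
kinked-beta backbones — beta-strand residues with one glycine-type kink
(positive phi) and a re-entry residue — whose kink/re-entry torsions were
tuned so that each namesake segment threads onto its own template with
low energy and so that non-kink side chains stay perpendicular to the
stacking axis (no forced clash with a residue's own strand images).  Two
kink registers are covered (window positions 3 and 2), so a window is
accommodated whenever either register aligns a small residue with the
kink.  The zipper template is an ideal parallel in-register pleated
strand (phi −120°, psi +120°), rise 4.8 Å, mating sheet generated by a
180° rotation about the fibril axis at 9 Å separation with a half-ish
(2.4 Å) axial stagger.  The 10 Å sheet separation of the kinked templates
reflects the looser mating of kinked sheets.

## Calibration

The screen's thresholds are calibrated quantities, not physical
constants; `scripts/calibrate.R` re-derives them and their values are
frozen into `ScreenConfig()`:

* `tauL = 61.6` — placed a quarter of the way up the gap between the
  glycine-rich control positives (the wild-type hexapeptide windows of
  the bundled mutation table plus the template namesakes) and scrambled
  charged/bulky negatives.
* `tauZ = 14.7` — an absolute-score gate on the mutant zipper energy,
  placed at median + 2 MAD of the conversion-capable anchor mutant
  energies.  The robust location matters: one anchor register (GYGGAS →
  GHGGAS) is dominated by a wild-type tyrosine clash; its mutant energy
  measures relief of that clash, not zipper quality, and must not inflate
  the gate.
* `deltaMax = −0.25` — conversion requires the mutant to *improve* on the
  wild type by more than the rotamer-repacking noise scale (repacking two
  windows independently can differ by a few tenths of a unit without any
  physical signal).

A variant covered by several accepted windows is scored in every
register; the retained pair is the lowest mutant energy among
conversion-capable registers (`delta ≤ deltaMax`), falling back to the
lowest mutant energy overall.  The intent is "flag any conversion-capable
register": a mutation converts its LARKS if *some* zipper register both
improves on the wild type and scores as a good zipper in absolute terms.
Note the direction-of-effect claim for the KRT8 anchors (delta < 0 for
Y54H, G55A, G62C) is independent of the absolute gate: Y54H shows a large
negative delta (relief of the tyrosine-clash register) but its best
conversion-capable register does not pass `tauZ`.

## Synthetic data

The generators define the benchmark conditions:

* **Proteome** — proteins of 70–90 residues with a central low-complexity
  region (35 % of the length; G/S/Y-rich composition) inside globular
  flanks, mirroring how LCDs sit inside real proteins (KRT8's head domain
  is ~19 % of the protein).  Three kink-compatible windows are planted per
  protein inside the LCD: small-residue hexapeptides with a forced
  glycine at register 2 or 3.
* **Variants** — pathogenic-like rows replace a planted kink glycine with
  a zipper-promoting residue; benign-like rows apply conservative
  substitutions at positions drawn outside the planted windows.  The
  benign class is deliberately *zipper-propensity-preserving*: swaps that
  add side-chain bulk (G→S inside a LARKS is the pathogenic FUS G191S),
  remove charge or proline, or change beta-branching are genuinely
  aggregation-modulating and would contradict the class's own ground
  truth label, so the map is restricted to swaps such as T→S, S→A, A→G,
  V↔I (in flanks), K↔R and D↔E.
* **Idealized zippers** — two-sheet, four-strand pleated assemblies
  realizing any of the eight symmetry classes (strand polarity within
  sheets; which face each sheet presents at the interface; relative
  strand sense between sheets), with a seeded random rigid transform.
  The classifier's primary test is the exact round trip of all
  8 classes × 3 orientations.

What passing these benchmarks does *not* show: the generator's planted
windows are cleanly kink-compatible and its LCD composition is
stationary, so recovery rates here say nothing about detection power on
real proteomes with isoform ambiguity, compositional drift, or variants
whose effect is mediated by context outside the hexapeptide window.

## Stand-ins for the deposited structures

The three deposited KRT8 segment structures are not bundled; network
access is not assumed anywhere in the package.  `standinStructure()`
builds synthetic idealized assemblies from the *described* geometry of
each entry (class, strand polarity, extended positions), labelled as
synthetic in their `source` field.  Geometric analyses of these stand-ins
exercise the full measurement pipeline (dihedral measurement, sheet
detection, class assignment) but are consistency checks against the
construction, not re-measurements of crystallographic data.

## Numerical choices

* Threading is deterministic: fixed rotamer order, strict-improvement
  sweeps, lowest-index tie-breaks; repeated runs are bit-identical, and
  results are memoized on (window, template, weights).
* Energies are invariant (to < 1e−6) under rigid motion of a template's
  realized coordinates: fibril expansion first re-canonicalizes the
  strand frame (strand axis +x, stacking axis +z from the alternating
  carbonyls).
* Backbone construction is exact forward kinematics; re-measured phi/psi
  reproduce the input table to machine precision, and chirality follows
  the L-configuration (improper N-C-CA-CB = +122.6°).
* Conformation labels: extended when both |phi| and |psi| ≥ 155°
  (operationalizing "nearly |180°|"); pleated in phi ∈ [−150, −90],
  psi ∈ [90, 150]; kinked for positive phi or |psi| < 60°.
* Buried interface area uses deterministic Fibonacci sphere sampling
  (960 points/atom, probe 1.4 Å); doubling the density moves the result
  by well under 2 %.
* Problem sizes: the packing-oracle suite enumerates 3-residue windows
  over residues with ≤ 6 rotamers (≤ 216 states); the synthetic benchmark
  uses 12 proteins and 60 planted positives, which keeps the full screen
  in the minutes range on one CPU.

## Limitations

* The energy function is coarse by design; absolute energies are
  meaningless outside the package and only orderings are interpreted.
* The kinked templates are idealized stand-ins, not the published LARKS
  backbones; register coverage (kink at window positions 2/3) is smaller
  than a full per-position template set.
* Proline is penalized, not modeled flexibly; backbone relaxation,
  explicit solvent and electrostatics are out of scope.
* The variant interface is protein-coordinate missense rows only; no
  transcript mapping, no indels or structural variants.
* For triclinic multi-interface crystals, the classifier reports the
  dominant two-sheet interface it detects; weaker secondary interfaces
  are not enumerated.
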