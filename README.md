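# larkscreen

Structure-based screening of missense mutations that convert reversible,
kinked amyloid segments (LARKS) into irreversible pleated steric zippers.

## The problem

Low-complexity domains of proteins such as FUS, hnRNPA1/A2, TDP-43 and
keratin-8 (KRT8) aggregate *reversibly* through LARKS — short
low-complexity amyloid-like kinked segments whose kinked β-strand
backbone limits the adhesion between mated β-sheets.  Pathogenic amyloid
instead builds *steric zippers*: two pleated β-sheets whose side chains
interdigitate.  A single missense substitution inside a LARKS — typically
replacing a kink glycine with a bulkier residue — can convert the kinked
motif into a zipper-competent pleated segment and turn functional,
reversible assembly into disease-associated aggregation.  The motivating
case is the KRT8 head domain, where the variants Y54H, G55A and G62C
(associated with liver disease) sit inside glycine-rich LARKS, and fibril
structures of the wild-type and mutant segments show the kinked/extended
→ pleated conversion directly.

`larkscreen` is for structural bioinformaticians who want to run that
screen on protein sequences and variant tables, and to analyze fibril
structures geometrically.

## The method

For a protein sequence `s` and window length `k = 6`:

1. **LARKS scan.** Every window `w` is threaded (fixed backbone, discrete
   rotamer packing) onto three kinked templates; the LARKS energy is
   `E_L(w) = min_t E(w | t)` and `w` is accepted when `E_L(w) ≤ τ_L`.
2. **Variant mapping.** Each missense variant is intersected with the
   accepted windows covering its position.
3. **Conversion scoring.** Wild-type and mutant windows are threaded onto
   a pleated steric-zipper template; with
   `ΔE = E_zip(mut) − E_zip(wt)`, a variant is *converted* when some
   covering register satisfies `ΔE ≤ δ_max` and `E_zip(mut) ≤ τ_Z` — a
   decrease in zipper energy both relative to the wild type and in
   absolute score.

The threading energy is an original four-term function (soft repulsion,
capped attraction, pairwise desolvation, geometric hydrogen bonds) in
arbitrary units; the identity
`E = w_rep·E_rep + w_att·E_att + w_solv·E_solv + w_hb·E_hb` holds
exactly, and only orderings and thresholded calls are interpreted.
Thresholds (`τ_L`, `τ_Z`, `δ_max`) are calibrated constants derived by
`scripts/calibrate.R` from bundled control sets.

The geometry half classifies fibril structures: strand/sheet detection,
steric-zipper class assignment (classes 1–8 from within-sheet polarity,
face packing and sheet polarity), pleated / extended / kinked backbone
labels from φ/ψ, and buried interface area (Shrake–Rupley).

## Worked example

```r
library(larkscreen)

fx  <- referenceFixtures()          # bundled KRT8 head domain + variants
cfg <- ScreenConfig()               # calibrated thresholds

rep <- runScreen(fx$proteins["KRT8"],
                 fx$variants[fx$variants$protein_id == "KRT8", ], cfg)
rep@calls[, c("position", "wt", "mut", "wt_window", "mut_window",
              "delta", "converted")]
```

```
  position wt mut wt_window mut_window        delta converted
1       54  Y   H    GYGGAS     GHGGAS -157.5836742     FALSE
2       55  G   A    YGGASG     YAGASG   -0.4751478      TRUE
3       62  G   C    SGMGGI     SGMGCI   -0.8400372      TRUE
```

All three KRT8 variants are matched to accepted LARKS windows and show a
*decrease* in zipper energy relative to the wild type (`delta < 0`), the
direction-of-effect expected for conversion-promoting mutations.  G55A
and G62C also pass the absolute-score gate; Y54H's large negative delta
reflects relief of a tyrosine clash in its best conversion-capable
register, which remains above `τ_Z`.

Geometric analysis of an idealized fibril assembly:

```r
z <- makeIdealZipperStructure(2, "SGMGCI", seed = 1)
classifyZipper(z$structure)
#> Steric zipper class 2 (parallel, face-to-back, up-up)
```

## Package tour

* `builtinTemplates()`, `buildBackbone()`, `expandFibril()` — fixed
  backbones and fibril context
* `threadWindow()`, `graftSequence()`, `packSideChains()`,
  `computeEnergy()` — the threading engine
* `scanLarks()`, `mapVariantsToLarks()`, `scoreZipperPair()`,
  `runScreen()`, `mutationHeatmap()`, `comparePathogenicBenign()`,
  `residueContextEnrichment()` — the mutation screen
* `assignStrands()`, `classifyZipper()`, `pleatProfile()`,
  `buriedInterfaceArea()` — fibril geometry
* `generateSyntheticProteome()`, `generateSyntheticVariants()`,
  `makeIdealZipperStructure()`, `standinStructure()` — seeded generators
* `readProteinFasta()`, `readVariantTable()`, `readStructurePdb()` — I/O

See the methods vignette (`vignettes/larks-zipper-screen.Rmd`) for the
model, its assumptions, calibration, and limitations.
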