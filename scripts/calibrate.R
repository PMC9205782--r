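#!/usr/bin/env Rscript
# Re-derives the shipped acceptance thresholds (tauL, tauZ) from the
# bundled control sets and anchor pairs; the values printed here are the
# ones frozen into ScreenConfig()'s defaults.
#
# Usage: Rscript scripts/calibrate.R

suppressPackageStartupMessages(library(larkscreen))

cal <- calibrateThresholds()
cat(sprintf("tauL (LARKS acceptance threshold):   %.2f\n", cal$tauL))
cat(sprintf("tauZ (zipper absolute-score gate):   %.2f\n", cal$tauZ))
cat("\ncontrol energies (min over kinked templates):\n")
cat("  positives:", paste(round(sort(cal$energies$positives), 1),
                          collapse = " "), "\n")
cat("  negatives:", paste(round(sort(cal$energies$negatives), 1),
                          collapse = " "), "\n")
cat("\nanchor zipper energies (wild type -> mutant):\n")
print(data.frame(wt = round(cal$energies$anchor_wt, 2),
                 mut = round(cal$energies$anchor_mutants, 2)))
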