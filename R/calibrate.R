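# Threshold calibration.  The screen's acceptance thresholds are not
# physical constants: they are fixed against two control sets (glycine-rich
# segment positives vs scrambled charged/bulky negatives) and the
# wild-type/mutant anchor pairs, then shipped as versioned package
# defaults (see ScreenConfig).  scripts/calibrate.R re-derives them.

#' Calibrate the screen thresholds from control sequences
#'
#' \code{tauL} is placed one quarter of the way up the gap between the
#' highest positive that still lies below every negative and the minimum
#' negative energy.  \code{tauZ} is placed above the mutant zipper
#' placed at median + 2 MAD of the mutant zipper energies of the
#' conversion-capable anchor registers (those whose mutant scores at least
#' one energy unit below the wild type); the robust location keeps
#' clash-dominated outlier registers from inflating the absolute-score
#' gate.
#'
#' @param positives character vector of LARKS-positive hexapeptides
#' @param negatives character vector of LARKS-negative hexapeptides
#' @param anchors data.frame with columns \code{wt_window},
#'   \code{mut_window} (wild-type/mutant zipper pairs expected to convert)
#' @param config a \code{\linkS4class{ScreenConfig}} providing weights and
#'   context (its thresholds are ignored)
#' @param templates template list
#' @return list: \code{tauL}, \code{tauZ}, \code{energies} (the control
#'   energies behind the choice)
#' @export
calibrateThresholds <- function(positives = calibrationControls()$positives,
                                negatives = calibrationControls()$negatives,
                                anchors = referenceFixtures()$mutation_table[
                                  referenceFixtures()$mutation_table$protein
                                  %in% c("KRT8", "FUS"), ],
                                config = ScreenConfig(),
                                templates = builtinTemplates()) {
  larks <- Filter(function(t) t@category == "LARKS", templates)
  zipper <- Filter(function(t) t@category == "zipper", templates)[[1L]]
  larksE <- function(w) min(vapply(larks, function(t)
    threaded_energy(w, t, config), 0))
  pos <- vapply(positives, larksE, 0)
  neg <- vapply(negatives, larksE, 0)
  lo <- max(pos[pos < min(neg)])
  tauL <- lo + 0.25 * (min(neg) - lo)

  wtE <- vapply(anchors$wt_window, function(w)
    threaded_energy(w, zipper, config), 0)
  mutE <- vapply(anchors$mut_window, function(w)
    threaded_energy(w, zipper, config), 0)
  capable <- (wtE - mutE) >= 1    # registers with a substantial decrease
  if (!any(capable))
    stop("no anchor pair shows a zipper-energy decrease; cannot calibrate")
  # robust absolute-score threshold: clash-dominated registers (whose large
  # energies reflect the wild type's incompatibility, not zipper quality)
  # must not inflate it
  mc <- mutE[capable]
  tauZ <- stats::median(mc) + 2 * stats::mad(mc)

  list(tauL = tauL, tauZ = tauZ,
       energies = list(positives = pos, negatives = neg,
                       anchor_wt = wtE, anchor_mutants = mutE))
}
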