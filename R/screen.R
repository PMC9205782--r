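# The end-to-end mutation screen: scan proteins for LARKS windows, map
# missense variants onto accepted windows, thread wild-type and mutant
# windows onto the pleated zipper template, and call conversions from the
# zipper-energy difference.

#' @title ScreenConfig: thresholds and settings of the mutation screen
#' @description Holds the calibrated acceptance thresholds (see
#' \code{\link{calibrateThresholds}}), the window length, the energy
#' weights, and the fibril-context settings used for threading.
#' @slot tauL LARKS acceptance threshold: a window is a LARKS when its best
#'   kinked-template energy is at most \code{tauL}
#' @slot tauZ zipper threshold: a mutant window can support a zipper when
#'   its zipper energy is at most \code{tauZ}
#' @slot deltaMax conversion threshold on \code{delta = E_mut - E_wt}
#'   (at most 0; strictly negative so that a null substitution never
#'   converts)
#' @slot k window length (the template length, 6)
#' @slot weights energy weights (named: rep, att, solv, hb)
#' @slot nStrands strands per sheet in the threading context
#' @slot maxCycles packing sweep limit
#' @export
setClass("ScreenConfig",
  representation(tauL = "numeric", tauZ = "numeric", deltaMax = "numeric",
                 k = "integer", weights = "numeric", nStrands = "integer",
                 maxCycles = "integer"))

setValidity("ScreenConfig", function(object) {
  if (object@deltaMax > 0) return("deltaMax must be <= 0")
  if (object@k < 4L) return("window length k must be >= 4")
  TRUE
})

setMethod("show", "ScreenConfig", function(object) {
  cat(sprintf("ScreenConfig: tauL %.1f, tauZ %.1f, deltaMax %g, k %d\n",
              object@tauL, object@tauZ, object@deltaMax, object@k))
})

# Calibrated defaults: fixed by scripts/calibrate.R against the bundled
# control sets (glycine-rich segment positives vs scrambled charged/bulky
# negatives); see the methods vignette.
CALIBRATED_TAU_L <- 61.63
CALIBRATED_TAU_Z <- 14.71
CALIBRATED_DELTA_MAX <- -0.25   # below the rotamer-repacking noise scale
CALIBRATED_WEIGHTS <- c(rep = 3, att = 0.2, solv = 0.5, hb = 1.5)

#' Construct a ScreenConfig
#' @param tauL,tauZ,deltaMax acceptance thresholds (calibrated defaults)
#' @param k window length
#' @param weights energy weights
#' @param nStrands strands per sheet
#' @param maxCycles packing sweep limit
#' @return a \code{\linkS4class{ScreenConfig}}
#' @export
ScreenConfig <- function(tauL = CALIBRATED_TAU_L, tauZ = CALIBRATED_TAU_Z,
                         deltaMax = CALIBRATED_DELTA_MAX, k = 6L,
                         weights = CALIBRATED_WEIGHTS, nStrands = 5L,
                         maxCycles = 10L) {
  methods::new("ScreenConfig", tauL = tauL, tauZ = tauZ,
               deltaMax = deltaMax, k = as.integer(k), weights = weights,
               nStrands = as.integer(nStrands),
               maxCycles = as.integer(maxCycles))
}

#' @title SequenceWindow: a k-residue slice of a protein
#' @slot proteinId protein accession
#' @slot start,end 1-based inclusive residue numbers (protein numbering,
#'   respecting the record's numbering offset)
#' @slot sequence the window's letters
#' @export
setClass("SequenceWindow",
  representation(proteinId = "character", start = "integer",
                 end = "integer", sequence = "character"))

setValidity("SequenceWindow", function(object) {
  if (object@end - object@start + 1L != nchar(object@sequence))
    return("end - start + 1 must equal the sequence length")
  TRUE
})

setMethod("show", "SequenceWindow", function(object) {
  cat(sprintf("%s_%d-%d %s\n", object@proteinId, object@start, object@end,
              object@sequence))
})

#' Extract a sequence window from a protein
#'
#' Coordinates are residue numbers under the protein's numbering offset
#' (e.g. a record whose printed sequence starts at residue 2 yields window
#' 58-64 from characters 57..63).
#'
#' @param protein a \code{\linkS4class{ProteinRecord}}
#' @param start,end 1-based inclusive residue numbers
#' @return a \code{\linkS4class{SequenceWindow}}
#' @export
extractWindow <- function(protein, start, end) {
  lo <- protein@offset
  hi <- protein@offset + nchar(protein@sequence) - 1L
  if (start < lo || end > hi || start > end)
    stop("window ", start, "-", end, " outside the numbered range ",
         lo, "-", hi, " of ", protein@id)
  s <- substr(protein@sequence, start - lo + 1L, end - lo + 1L)
  methods::new("SequenceWindow", proteinId = protein@id,
               start = as.integer(start), end = as.integer(end),
               sequence = s)
}

#' Apply a missense variant to a sequence window
#'
#' The variant's stated wild-type residue must match the window letter at
#' the variant position; a mismatch signals a numbering or isoform problem
#' and raises an error.
#'
#' @param window a \code{\linkS4class{SequenceWindow}}
#' @param variant one-row data.frame with columns \code{position},
#'   \code{wt}, \code{mut} (protein numbering)
#' @return the mutated \code{SequenceWindow} (same coordinates)
#' @export
applyMutation <- function(window, variant) {
  pos <- as.integer(variant$position)
  if (pos < window@start || pos > window@end)
    stop("variant position ", pos, " outside window ", window@start, "-",
         window@end)
  i <- pos - window@start + 1L
  have <- substr(window@sequence, i, i)
  if (have != variant$wt)
    stop("wild-type mismatch at position ", pos, ": window has '", have,
         "', variant states '", variant$wt,
         "' (check the numbering offset)")
  s <- window@sequence
  substr(s, i, i) <- as.character(variant$mut)
  methods::new("SequenceWindow", proteinId = window@proteinId,
               start = window@start, end = window@end, sequence = s)
}

# ---- threading cache --------------------------------------------------------

.thread_cache <- new.env(parent = emptyenv())

# Memoized total energy of a window on a template (threading is
# deterministic, so caching cannot change results).
#' @keywords internal
threaded_energy <- function(window, template, config) {
  key <- paste(window, template@name,
               paste(config@weights, collapse = ","), config@nStrands,
               sep = "|")
  hit <- .thread_cache[[key]]
  if (!is.null(hit)) return(hit)
  e <- totalEnergy(threadWindow(window, template,
                                weights = config@weights,
                                nStrands = config@nStrands,
                                maxCycles = config@maxCycles))
  assign(key, e, envir = .thread_cache)
  e
}

# ---- scanning and mapping ---------------------------------------------------

#' Scan a protein for LARKS windows
#'
#' Threads every sliding window (stride 1) onto all three kinked templates;
#' \code{E_larks} is the minimum of the three energies and a window is
#' accepted when \code{E_larks <= tauL}.  Windows containing \code{X} are
#' skipped with a warning.
#'
#' @param protein a \code{\linkS4class{ProteinRecord}}
#' @param templates list of templates from \code{\link{builtinTemplates}}
#'   (the LARKS members are used)
#' @param config a \code{\linkS4class{ScreenConfig}}
#' @return data.frame with one row per evaluated window: \code{protein_id},
#'   \code{start}, \code{end}, \code{sequence}, \code{best_template},
#'   \code{E_larks}, \code{accepted}
#' @export
scanLarks <- function(protein, templates = builtinTemplates(),
                      config = ScreenConfig()) {
  larks <- Filter(function(t) t@category == "LARKS", templates)
  k <- config@k
  L <- nchar(protein@sequence)
  if (L < k) stop("protein ", protein@id, " shorter than the window length")
  n_skip <- 0L
  rows <- list()
  for (i in seq_len(L - k + 1L)) {
    start <- protein@offset + i - 1L
    win <- extractWindow(protein, start, start + k - 1L)
    if (grepl("X", win@sequence, fixed = TRUE)) {
      n_skip <- n_skip + 1L
      next
    }
    es <- vapply(larks, function(t) threaded_energy(win@sequence, t, config),
                 0)
    b <- which.min(es)
    rows[[length(rows) + 1L]] <-
      data.frame(protein_id = protein@id, start = win@start,
                 end = win@end, sequence = win@sequence,
                 best_template = names(larks)[b], E_larks = es[b],
                 accepted = es[b] <= config@tauL,
                 stringsAsFactors = FALSE)
  }
  if (n_skip > 0L)
    warning(n_skip, " window(s) containing X skipped in ", protein@id)
  if (length(rows) == 0L) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      best_template = character(0), E_larks = numeric(0),
                      accepted = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank accepted LARKS windows
#'
#' Orders the accepted windows of one or more scan tables by ascending
#' LARKS energy (the strongest predicted LARKS first) and returns the top
#' \code{n}.  Ranking by the threading energy itself is the package's
#' stated convention.
#'
#' @param larksCalls scan results (rows from \code{\link{scanLarks}})
#' @param n number of windows to return (default all accepted)
#' @return the top-ranked rows with an added \code{rank} column
#' @export
rankLarks <- function(larksCalls, n = Inf) {
  acc <- larksCalls[larksCalls$accepted, , drop = FALSE]
  acc <- acc[order(acc$E_larks), , drop = FALSE]
  acc$rank <- seq_len(nrow(acc))
  utils::head(acc, n)
}

#' Map variants onto accepted LARKS windows
#'
#' A variant matches every accepted window of its protein whose
#' \code{[start, end]} interval contains the variant position.  Variants
#' with no matching window are excluded (and counted in the
#' \code{n_unmatched} attribute).
#'
#' @param variants variant data.frame (see \code{\link{readVariantTable}})
#' @param larksCalls scan results (possibly several proteins' rows bound
#'   together)
#' @return list with one element per matched variant:
#'   \code{list(variant = <row>, windows = <data.frame>)}; attribute
#'   \code{n_unmatched} counts excluded variants
#' @export
mapVariantsToLarks <- function(variants, larksCalls) {
  acc <- larksCalls[larksCalls$accepted, , drop = FALSE]
  out <- list()
  unmatched <- 0L
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    w <- acc[acc$protein_id == v$protein_id & acc$start <= v$position &
             acc$end >= v$position, , drop = FALSE]
    if (nrow(w) == 0L) {
      unmatched <- unmatched + 1L
      next
    }
    out[[length(out) + 1L]] <- list(variant = v, windows = w)
  }
  attr(out, "n_unmatched") <- unmatched
  out
}

# ---- zipper scoring ---------------------------------------------------------

#' Score a wild-type/mutant window pair on the zipper template
#'
#' Threads both windows onto the pleated zipper template with identical
#' settings and reports the energies, their difference
#' \code{delta = E_zip_mut - E_zip_wt}, and the conversion call
#' (\code{converted} iff \code{E_zip_mut <= tauZ} and
#' \code{delta <= deltaMax}).
#'
#' @param variant one-row variant data.frame
#' @param window the wild-type \code{\linkS4class{SequenceWindow}}
#' @param zipperTemplate the pleated template
#' @param config a \code{\linkS4class{ScreenConfig}}
#' @return one-row data.frame: window coordinates, \code{wt_window},
#'   \code{mut_window}, \code{E_zip_wt}, \code{E_zip_mut}, \code{delta},
#'   \code{converted}
#' @export
scoreZipperPair <- function(variant, window,
                            zipperTemplate = builtinTemplates()$ZIPPER_P1,
                            config = ScreenConfig()) {
  mut <- applyMutation(window, variant)
  e_wt <- threaded_energy(window@sequence, zipperTemplate, config)
  e_mut <- threaded_energy(mut@sequence, zipperTemplate, config)
  delta <- e_mut - e_wt
  data.frame(protein_id = window@proteinId, start = window@start,
             end = window@end, wt_window = window@sequence,
             mut_window = mut@sequence, E_zip_wt = e_wt,
             E_zip_mut = e_mut, delta = delta,
             converted = (e_mut <= config@tauZ) & (delta <= config@deltaMax),
             stringsAsFactors = FALSE)
}

# Retained pair for a variant covered by several windows: lowest E_zip_mut
# among windows showing a conversion-capable register (delta <= deltaMax);
# if no register qualifies, lowest E_zip_mut overall (the call is negative
# either way, so the choice only fixes which energies are reported).
#' @keywords internal
retain_pair <- function(pairs, config) {
  capable <- pairs[pairs$delta <= config@deltaMax, , drop = FALSE]
  pool <- if (nrow(capable) > 0L) capable else pairs
  pool[which.min(pool$E_zip_mut), , drop = FALSE]
}

# ---- descriptive summaries --------------------------------------------------

#' Count wild-type/mutant residue transitions
#'
#' @param variants variant data.frame with columns \code{wt}, \code{mut}
#' @return 20 x 20 integer matrix (rows: wild type, columns: mutant);
#'   the diagonal is structurally zero
#' @export
mutationHeatmap <- function(variants) {
  m <- matrix(0L, 20L, 20L, dimnames = list(wt = AA1, mut = AA1))
  if (nrow(variants) > 0L) {
    tab <- table(factor(variants$wt, AA1), factor(variants$mut, AA1))
    m[] <- as.integer(tab)
  }
  m
}

#' Compare pathogenic and benign zipper-score distributions
#'
#' Descriptive only (no hypothesis test): per-group medians of the mutant
#' zipper energy and of delta, the fraction of converted calls, and a
#' scatter-ready table of (E_zip_mut, delta) points.
#'
#' @param pairsPathogenic,pairsBenign data.frames of retained zipper pairs
#'   (one row per variant, columns \code{E_zip_mut}, \code{delta},
#'   \code{converted})
#' @return list with \code{summary} (one row per group) and
#'   \code{scatter} (one row per input pair)
#' @export
comparePathogenicBenign <- function(pairsPathogenic, pairsBenign) {
  if (nrow(pairsPathogenic) == 0L || nrow(pairsBenign) == 0L)
    stop("both groups must be non-empty")
  grp <- function(df, label) {
    data.frame(group = label, n = nrow(df),
               median_E_zip_mut = stats::median(df$E_zip_mut),
               median_delta = stats::median(df$delta),
               fraction_converted = mean(df$converted),
               stringsAsFactors = FALSE)
  }
  scatter <- rbind(
    data.frame(group = "pathogenic",
               pairsPathogenic[, c("E_zip_mut", "delta", "converted")]),
    data.frame(group = "benign",
               pairsBenign[, c("E_zip_mut", "delta", "converted")]))
  rownames(scatter) <- NULL
  list(summary = rbind(grp(pairsPathogenic, "pathogenic"),
                       grp(pairsBenign, "benign")),
       scatter = scatter)
}

#' Residue-type enrichment of variant positions against a background
#'
#' For each residue type, the observed frequency among the variants'
#' wild-type (and, separately, mutant) residues divided by the supplied
#' background frequency.  Zero-background residues yield \code{NA} with the
#' \code{undefined} flag set.
#'
#' @param variants variant data.frame
#' @param background named numeric vector of residue frequencies (sums to
#'   1; e.g. beta-sheet or LARKS residue frequencies)
#' @return data.frame: \code{residue}, \code{wt_freq}, \code{mut_freq},
#'   \code{background}, \code{wt_enrichment}, \code{mut_enrichment},
#'   \code{undefined}
#' @export
residueContextEnrichment <- function(variants, background) {
  if (nrow(variants) == 0L)
    return(data.frame(residue = character(0), wt_freq = numeric(0),
                      mut_freq = numeric(0), background = numeric(0),
                      wt_enrichment = numeric(0),
                      mut_enrichment = numeric(0), undefined = logical(0)))
  bg <- background[AA1]
  wt <- as.numeric(table(factor(variants$wt, AA1))) / nrow(variants)
  mu <- as.numeric(table(factor(variants$mut, AA1))) / nrow(variants)
  undef <- is.na(bg) | bg == 0
  enr <- function(obs) ifelse(undef, NA_real_, obs / bg)
  if (any(undef))
    warning("zero background frequency for: ",
            paste(AA1[undef], collapse = ", "),
            "; enrichment reported as NA")
  data.frame(residue = AA1, wt_freq = wt, mut_freq = mu,
             background = as.numeric(bg), wt_enrichment = enr(wt),
             mut_enrichment = enr(mu), undefined = undef,
             stringsAsFactors = FALSE)
}

# ---- the full screen --------------------------------------------------------

#' @title ScreenReport: results of the end-to-end mutation screen
#' @slot calls data.frame, one row per scored variant: identity, retained
#'   window, \code{E_larks}, \code{E_zip_wt}, \code{E_zip_mut},
#'   \code{delta}, normalized columns, \code{converted}
#' @slot larks the LARKS scan table for all proteins
#' @slot rejected variants quarantined for wild-type/sequence mismatch
#' @slot unmatched number of variants outside all accepted windows
#' @slot heatmap 20 x 20 wild-type by mutant count matrix
#' @slot groupSummary pathogenic-vs-benign summary (empty data.frame when a
#'   group is absent)
#' @export
setClass("ScreenReport",
  representation(calls = "data.frame", larks = "data.frame",
                 rejected = "data.frame", unmatched = "integer",
                 heatmap = "matrix", groupSummary = "data.frame"))

setMethod("show", "ScreenReport", function(object) {
  cat(sprintf(paste0("ScreenReport: %d variant(s) scored, %d converted; ",
                     "%d LARKS window(s) accepted; %d rejected, ",
                     "%d unmatched\n"),
              nrow(object@calls), sum(object@calls$converted),
              sum(object@larks$accepted), nrow(object@rejected),
              object@unmatched))
})

#' Run the full mutation screen
#'
#' Composes the pipeline: LARKS scan over every protein, variant-to-window
#' mapping, wild-type/mutant zipper threading per covering window,
#' per-variant aggregation (see the methods vignette), conversion calls,
#' the wild-type/mutant transition heat map, and pathogenic-vs-benign
#' summaries.  Fully deterministic for a fixed configuration.
#'
#' Variants whose stated wild-type residue does not match the protein
#' sequence at the stated position are quarantined into the report's
#' \code{rejected} slot rather than silently dropped.
#'
#' @param proteins list of \code{\linkS4class{ProteinRecord}}
#' @param variants variant data.frame (see \code{\link{readVariantTable}})
#' @param config a \code{\linkS4class{ScreenConfig}}
#' @param templates template list (\code{\link{builtinTemplates}})
#' @return a \code{\linkS4class{ScreenReport}}
#' @export
runScreen <- function(proteins, variants, config = ScreenConfig(),
                      templates = builtinTemplates()) {
  zipper <- Filter(function(t) t@category == "zipper", templates)[[1L]]
  prot_ids <- vapply(proteins, function(p) p@id, "")
  names(proteins) <- prot_ids

  # quarantine variants that contradict the sequence
  ok <- rep(TRUE, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    p <- proteins[[v$protein_id]]
    if (is.null(p)) { ok[i] <- FALSE; next }
    lo <- p@offset; hi <- p@offset + nchar(p@sequence) - 1L
    if (v$position < lo || v$position > hi) { ok[i] <- FALSE; next }
    have <- substr(p@sequence, v$position - lo + 1L, v$position - lo + 1L)
    if (have != v$wt) ok[i] <- FALSE
  }
  rejected <- variants[!ok, , drop = FALSE]
  variants <- variants[ok, , drop = FALSE]

  larks <- do.call(rbind, lapply(proteins, scanLarks,
                                 templates = templates, config = config))
  rownames(larks) <- NULL
  mapping <- mapVariantsToLarks(variants, larks)

  if (length(mapping) == 0L)
    warning("no variant falls inside an accepted LARKS window")

  calls <- list()
  for (m in mapping) {
    v <- m$variant
    pairs <- do.call(rbind, lapply(seq_len(nrow(m$windows)), function(j) {
      wrow <- m$windows[j, ]
      win <- methods::new("SequenceWindow", proteinId = wrow$protein_id,
                          start = wrow$start, end = wrow$end,
                          sequence = wrow$sequence)
      cbind(scoreZipperPair(v, win, zipper, config),
            E_larks = wrow$E_larks)
    }))
    best <- retain_pair(pairs, config)
    calls[[length(calls) + 1L]] <-
      cbind(v[, c("protein_id", "position", "wt", "mut", "significance",
                  "source")],
            best[, c("start", "end", "wt_window", "mut_window", "E_larks",
                     "E_zip_wt", "E_zip_mut", "delta", "converted")],
            n_windows = nrow(pairs))
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(protein_id = character(0), position = integer(0),
               wt = character(0), mut = character(0),
               significance = character(0), source = character(0),
               start = integer(0), end = integer(0),
               wt_window = character(0), mut_window = character(0),
               E_larks = numeric(0), E_zip_wt = numeric(0),
               E_zip_mut = numeric(0), delta = numeric(0),
               converted = logical(0), n_windows = integer(0))
  rownames(calls) <- NULL

  # per-protein normalized zipper score (z-like: centred on the protein's
  # median mutant energy) alongside the raw one
  if (nrow(calls) > 0L) {
    med <- stats::ave(calls$E_zip_mut, calls$protein_id,
                      FUN = stats::median)
    calls$E_zip_mut_centred <- calls$E_zip_mut - med
  } else calls$E_zip_mut_centred <- numeric(0)

  gs <- data.frame()
  if (nrow(calls) > 0L &&
      all(c("pathogenic", "benign") %in% calls$significance)) {
    gs <- comparePathogenicBenign(
      calls[calls$significance == "pathogenic", ],
      calls[calls$significance == "benign", ])$summary
  }
  methods::new("ScreenReport", calls = calls, larks = larks,
               rejected = rejected,
               unmatched = attr(mapping, "n_unmatched"),
               heatmap = mutationHeatmap(variants), groupSummary = gs)
}

#' Write a screen report to TSV and JSON files
#'
#' Writes \code{<stem>_calls.tsv}, \code{<stem>_larks.tsv},
#' \code{<stem>_heatmap.tsv}, \code{<stem>_rejected.tsv} and a combined
#' \code{<stem>.json}.
#'
#' @param report a \code{\linkS4class{ScreenReport}}
#' @param stem output path stem
#' @return invisibly, the JSON path
#' @export
writeScreenReport <- function(report, stem) {
  utils::write.table(report@calls, paste0(stem, "_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report@larks, paste0(stem, "_larks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report@rejected, paste0(stem, "_rejected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report@heatmap, paste0(stem, "_heatmap.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  json <- paste0(stem, ".json")
  jsonlite::write_json(list(calls = report@calls,
                            n_larks_accepted = sum(report@larks$accepted),
                            unmatched = report@unmatched,
                            rejected = report@rejected,
                            group_summary = report@groupSummary),
                       json, auto_unbox = TRUE, digits = NA)
  invisible(json)
}
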