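# Seeded synthetic-data generators: low-complexity proteomes with planted
# LARKS windows, pathogenic-like and benign-like variant tables, and
# idealized two-sheet steric-zipper assemblies of all eight symmetry
# classes.  Every generator is a pure function of (spec, seed).

# typical globular composition for the flanks around the LCD
GLOBULAR_COMPOSITION <- local({
  p <- c(A = 0.08, R = 0.055, N = 0.04, D = 0.055, C = 0.015, Q = 0.04,
         E = 0.065, G = 0.07, H = 0.022, I = 0.06, L = 0.095, K = 0.06,
         M = 0.024, F = 0.04, P = 0.047, S = 0.066, T = 0.053, W = 0.011,
         Y = 0.03, V = 0.068)
  p / sum(p)
})

# default low-complexity (G/S/Y-rich) residue composition
LCD_COMPOSITION <- local({
  p <- c(G = 0.28, S = 0.20, Y = 0.09, A = 0.08, N = 0.06, Q = 0.05,
         T = 0.05, P = 0.04, R = 0.03, F = 0.03, V = 0.03, L = 0.02,
         M = 0.01, I = 0.01, D = 0.005, E = 0.005, K = 0.005, H = 0.005,
         W = 0.0025, C = 0.0025)
  p / sum(p)
})

# Conservative substitutions used for benign-like rows.  The class must be
# zipper-propensity-preserving for its own ground-truth label
# (expected_converted = FALSE) to be true, so it is restricted to swaps
# within the small/polar low-complexity alphabet that neither add
# side-chain bulk (adding atoms at an interdigitating interface is the
# conversion signal itself -- glycine-to-serine inside a LARKS is the
# pathogenic FUS G191S) nor remove charge, proline or beta-branching
# (classic aggregation-promoting changes).
# sample() treats a length-1 numeric as 1:x; this helper always samples
# from the supplied set
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

BENIGN_SUBS <- c(T = "S", S = "A", A = "G", N = "S", M = "L", C = "A",
                 W = "F", F = "Y",
                 # charge- and branching-preserving swaps for the globular
                 # flank alphabet
                 V = "I", I = "V", L = "I", K = "R", R = "K", E = "D",
                 D = "E", Q = "E")

#' @title SyntheticSpec: parameters of the synthetic-data generators
#' @slot seed RNG seed; identical (spec, seed) gives identical output
#' @slot nProteins number of proteins
#' @slot lengthRange min/max protein length (uniform)
#' @slot composition LCD-region residue probabilities (named over the 20
#'   standard residues)
#' @slot flankComposition residue probabilities of the globular flanks
#'   surrounding the low-complexity region
#' @slot lcdFraction fraction of each protein occupied by the central
#'   low-complexity region
#' @slot nPlantedPerProtein LARKS windows planted per protein
#' @slot plantedAlphabet residue probabilities inside planted windows
#' @slot kinkRegisters window positions eligible to carry the planted kink
#'   glycine
#' @slot nPathogenic,nBenign variant counts per class
#' @slot pathogenicSubs residues substituted for the kink glycine in
#'   pathogenic-like rows
#' @slot pathogenicInPlantedFrac fraction of pathogenic-like rows forced
#'   inside planted windows
#' @export
setClass("SyntheticSpec",
  representation(seed = "integer", nProteins = "integer",
                 lengthRange = "integer", composition = "numeric",
                 flankComposition = "numeric", lcdFraction = "numeric",
                 nPlantedPerProtein = "integer",
                 plantedAlphabet = "numeric", kinkRegisters = "integer",
                 nPathogenic = "integer", nBenign = "integer",
                 pathogenicSubs = "character",
                 pathogenicInPlantedFrac = "numeric"))

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %d proteins (%d-%d aa), %d planted ",
                     "windows each; %d pathogenic-like + %d benign-like ",
                     "variants; seed %d\n"),
              object@nProteins, object@lengthRange[1L],
              object@lengthRange[2L], object@nPlantedPerProtein,
              object@nPathogenic, object@nBenign, object@seed))
})

#' Construct a SyntheticSpec
#' @param seed RNG seed
#' @param nProteins number of proteins
#' @param lengthRange length-2 integer vector, protein length bounds
#' @param composition LCD-region residue probabilities
#' @param flankComposition residue probabilities of the globular flanks
#' @param lcdFraction fraction of the protein occupied by the LCD
#' @param nPlantedPerProtein planted LARKS windows per protein
#' @param plantedAlphabet residue probabilities inside planted windows
#' @param kinkRegisters eligible kink positions within a window
#' @param nPathogenic,nBenign variant counts
#' @param pathogenicSubs kink-glycine replacements for pathogenic-like rows
#' @param pathogenicInPlantedFrac fraction of pathogenic-like rows inside
#'   planted windows
#' @return a \code{\linkS4class{SyntheticSpec}}
#' @export
SyntheticSpec <- function(seed = 1L, nProteins = 12L,
                          lengthRange = c(70L, 90L),
                          composition = LCD_COMPOSITION,
                          flankComposition = GLOBULAR_COMPOSITION,
                          lcdFraction = 0.35,
                          nPlantedPerProtein = 3L,
                          plantedAlphabet = c(G = 0.55, S = 0.25, A = 0.20),
                          kinkRegisters = c(2L, 3L),
                          nPathogenic = 60L, nBenign = 60L,
                          pathogenicSubs = c("A", "C", "V", "S", "H"),
                          pathogenicInPlantedFrac = 1.0) {
  methods::new("SyntheticSpec", seed = as.integer(seed),
               nProteins = as.integer(nProteins),
               lengthRange = as.integer(lengthRange),
               composition = composition,
               flankComposition = flankComposition,
               lcdFraction = lcdFraction,
               nPlantedPerProtein = as.integer(nPlantedPerProtein),
               plantedAlphabet = plantedAlphabet,
               kinkRegisters = as.integer(kinkRegisters),
               nPathogenic = as.integer(nPathogenic),
               nBenign = as.integer(nBenign),
               pathogenicSubs = pathogenicSubs,
               pathogenicInPlantedFrac = pathogenicInPlantedFrac)
}

#' Generate a synthetic proteome of LCD-bearing proteins with planted LARKS
#'
#' Each protein is a central low-complexity (G/S/Y-rich) region flanked by
#' globular-composition sequence, mirroring how low-complexity domains sit
#' inside real proteins.  Planted windows (kink-compatible: drawn from a
#' small-residue alphabet with a forced glycine at a kink register) are
#' inserted inside the LCD at recorded, non-overlapping positions.
#'
#' @param spec a \code{\linkS4class{SyntheticSpec}}
#' @return list: \code{proteins} (list of
#'   \code{\linkS4class{ProteinRecord}}), \code{truth} (data.frame:
#'   \code{protein_id}, \code{start}, \code{end}, \code{sequence},
#'   \code{kink_pos}), \code{lcd} (data.frame of per-protein LCD bounds)
#' @export
generateSyntheticProteome <- function(spec) {
  k <- 6L
  if (floor(spec@lengthRange[1L] * spec@lcdFraction) <
      k * (spec@nPlantedPerProtein + 1L))
    stop("LCD regions too short to hold ", spec@nPlantedPerProtein,
         " planted windows")
  set.seed(spec@seed)
  proteins <- list()
  truth <- list()
  lcd <- list()
  for (i in seq_len(spec@nProteins)) {
    id <- sprintf("SYN%03d", i)
    L <- sample1(seq(spec@lengthRange[1L], spec@lengthRange[2L]))
    n_lcd <- floor(L * spec@lcdFraction)
    lcd_start <- sample(seq_len(L - n_lcd + 1L), 1L)
    lcd_end <- lcd_start + n_lcd - 1L
    seqv <- sample(names(spec@flankComposition), L, replace = TRUE,
                   prob = spec@flankComposition)
    seqv[lcd_start:lcd_end] <- sample(names(spec@composition), n_lcd,
                                      replace = TRUE,
                                      prob = spec@composition)
    lcd[[i]] <- data.frame(protein_id = id, lcd_start = lcd_start,
                           lcd_end = lcd_end, stringsAsFactors = FALSE)
    # non-overlapping planted slots inside the LCD: sample sorted starts
    # with pairwise spacing >= k via the gap transform (always feasible
    # when the LCD passes the length check above)
    np <- spec@nPlantedPerProtein
    A <- lcd_end - k + 1L - lcd_start + 1L
    base <- sort(sample(seq_len(A - (np - 1L) * k), np))
    slots <- lcd_start - 1L + base + (seq_len(np) - 1L) * k
    for (s in sort(slots)) {
      win <- sample(names(spec@plantedAlphabet), k, replace = TRUE,
                    prob = spec@plantedAlphabet)
      reg <- sample1(spec@kinkRegisters)
      win[reg] <- "G"
      seqv[s:(s + k - 1L)] <- win
      truth[[length(truth) + 1L]] <-
        data.frame(protein_id = id, start = s, end = s + k - 1L,
                   sequence = paste(win, collapse = ""),
                   kink_pos = s + reg - 1L, stringsAsFactors = FALSE)
    }
    proteins[[id]] <- ProteinRecord(id, paste(seqv, collapse = ""))
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(proteins = proteins, truth = truth, lcd = do.call(rbind, lcd))
}

#' Generate synthetic variant tables with ground truth
#'
#' Pathogenic-like rows replace the kink glycine of a planted window with a
#' zipper-promoting residue; benign-like rows apply conservative
#' substitutions at positions drawn uniformly outside planted windows.
#' Every row's wild-type residue is consistent with the proteome.
#'
#' @param proteome result of \code{\link{generateSyntheticProteome}}
#' @param spec the same \code{\linkS4class{SyntheticSpec}}
#' @return list: \code{variants} (data.frame in variant-table format),
#'   \code{truth} (the variants plus \code{planted} and
#'   \code{expected_converted} columns)
#' @export
generateSyntheticVariants <- function(proteome, spec) {
  planted <- proteome$truth     # force the argument before seeding the RNG
  set.seed(spec@seed + 1L)
  rows <- list()
  # pathogenic-like: kink glycine of a planted window -> zipper-promoting;
  # planted rows are sampled without replacement over the
  # (window, substitution) product so the requested count is realized
  n_in <- round(spec@nPathogenic * spec@pathogenicInPlantedFrac)
  combos <- expand.grid(w = seq_len(nrow(planted)),
                        s = seq_along(spec@pathogenicSubs))
  if (n_in > nrow(combos))
    stop("nPathogenic exceeds the number of distinct planted ",
         "(window, substitution) pairs")
  pick <- combos[sample(nrow(combos), n_in), , drop = FALSE]
  for (i in seq_len(nrow(pick))) {
    w <- planted[pick$w[i], ]
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = w$protein_id, position = w$kink_pos, wt = "G",
      mut = spec@pathogenicSubs[pick$s[i]],
      significance = "pathogenic", source = "synthetic",
      planted = TRUE, stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec@nPathogenic - n_in)) {
    pid <- sample(names(proteome$proteins), 1L)
    p <- proteome$proteins[[pid]]
    gs <- which(strsplit(p@sequence, "")[[1L]] == "G")
    if (length(gs) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = pid, position = sample(gs, 1L), wt = "G",
      mut = sample(spec@pathogenicSubs, 1L),
      significance = "pathogenic", source = "synthetic",
      planted = FALSE, stringsAsFactors = FALSE)
  }
  # benign-like: conservative substitution at a uniform non-planted site
  for (i in seq_len(spec@nBenign)) {
    pid <- sample1(names(proteome$proteins))
    p <- proteome$proteins[[pid]]
    seqv <- strsplit(p@sequence, "")[[1L]]
    inside <- rep(FALSE, length(seqv))
    pw <- planted[planted$protein_id == pid, ]
    for (j in seq_len(nrow(pw))) inside[pw$start[j]:pw$end[j]] <- TRUE
    eligible <- which(!inside & seqv %in% names(BENIGN_SUBS))
    if (length(eligible) == 0L) next
    pos <- sample1(eligible)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = pid, position = pos, wt = seqv[pos],
      mut = unname(BENIGN_SUBS[seqv[pos]]),
      significance = "benign", source = "synthetic",
      planted = FALSE, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  truth <- truth[!duplicated(truth[, c("protein_id", "position", "mut")]), ]
  rownames(truth) <- NULL
  truth$expected_converted <- truth$significance == "pathogenic" &
    truth$planted
  list(variants = truth[, c("protein_id", "position", "wt", "mut",
                            "significance", "source")],
       truth = truth)
}

# ---- idealized zipper assemblies -------------------------------------------

# full-atom strand in the canonical template frame, side chains at the
# first library rotamer
#' @keywords internal
build_full_strand <- function(sequence, dihedrals = NULL) {
  seqv <- strsplit(sequence, "")[[1L]]
  n <- length(seqv)
  if (is.null(dihedrals)) dihedrals <- idealBetaDihedrals(n)
  bb <- buildBackbone(dihedrals)
  lib <- rotamerLibrary()
  out <- list()
  for (i in seq_len(n)) {
    aa <- seqv[i]
    cm <- bb[[i]]
    nm <- if (aa == "G") c("N", "CA", "C", "O") else c("N", "CA", "C", "O",
                                                       "CB")
    coords <- cm[nm, , drop = FALSE]
    if (aa != "G") {
      sc <- build_sidechain(aa, lib[[aa]][[1L]], cm["N", ], cm["CA", ],
                            cm["C", ], cm["CB", ])
      coords <- rbind(coords, sc)
    }
    out[[i]] <- coords
  }
  out
}

# the three binary attributes of each class (classical taxonomy)
#' @keywords internal
class_attributes <- function(classNumber) {
  hit <- ZIPPER_CLASS_TABLE[ZIPPER_CLASS_TABLE$class == classNumber, ]
  if (nrow(hit) != 1L) stop("class number must be in 1..8")
  list(within = hit$within, polarity = hit$polarity, face = hit$face)
}

#' Build an idealized steric-zipper assembly of a given class
#'
#' Constructs a two-sheet assembly (default 4 strands per sheet) of
#' pleated strands carrying \code{sequence}, realizing the three binary
#' attributes of the requested class: strand stacking within sheets,
#' the face each sheet presents at the interface, and the relative strand
#' sense between sheets.  A seeded random rigid-body transform is applied
#' to the whole assembly; the planted attributes are returned as ground
#' truth.
#'
#' @param classNumber steric-zipper class, 1..8
#' @param sequence strand sequence (6 or 7 residues)
#' @param seed RNG seed for the rigid-body transform
#' @param nStrandsPerSheet strands per sheet (>= 2)
#' @param sheetSep inter-sheet distance (angstrom)
#' @param stagger axial offset of the mating sheet (angstrom)
#' @param rise axial rise (angstrom)
#' @param startResno first residue number
#' @param dihedrals optional per-residue phi/psi/omega override
#' @return list: \code{structure} (a
#'   \code{\linkS4class{StructureModel}}), \code{truth} (attributes and
#'   class number)
#' @examples
#' z <- makeIdealZipperStructure(2, "SGMGCI", seed = 1)
#' z$truth$class
#' @export
makeIdealZipperStructure <- function(classNumber, sequence, seed = 1L,
                                     nStrandsPerSheet = 4L, sheetSep = 9.5,
                                     stagger = 1.2, rise = 4.8,
                                     startResno = 1L, dihedrals = NULL) {
  if (!classNumber %in% 1:8) stop("class number must be in 1..8")
  if (!nchar(sequence) %in% c(6L, 7L))
    stop("sequence must have 6 or 7 residues")
  at <- class_attributes(classNumber)
  strand <- build_full_strand(sequence, dihedrals)
  seqv <- strsplit(sequence, "")[[1L]]

  Rz <- rotation_about_axis(c(0, 0, 1), 180)
  Rx <- rotation_about_axis(c(1, 0, 0), 180)
  Ry <- rotation_about_axis(c(0, 1, 0), 180)
  Id <- diag(3)

  anti <- at$within == "antiparallel"
  sigma <- if (at$polarity == "up-up") 1 else -1
  front <- at$face == "face-to-face"

  place <- function(R, t, chain) {
    do.call(rbind, lapply(seq_along(strand), function(i) {
      m <- apply_rigid(strand[[i]], R, t)
      data.frame(chain = chain, resno = startResno + i - 1L,
                 resname = unname(AA3[seqv[i]]), atom = rownames(strand[[i]]),
                 element = vapply(rownames(strand[[i]]), element_of, ""),
                 x = m[, 1L], y = m[, 2L], z = m[, 3L], occupancy = 1,
                 record = "polymer", stringsAsFactors = FALSE)
    }))
  }

  chains <- c(LETTERS[seq_len(nStrandsPerSheet)],
              LETTERS[nStrandsPerSheet + seq_len(nStrandsPerSheet)])
  rows <- list()
  for (k in seq_len(nStrandsPerSheet) - 1L) {
    R <- if (anti && k %% 2L == 1L) Ry else Id
    rows[[length(rows) + 1L]] <- place(R, c(0, 0, k * rise),
                                       chains[k + 1L])
  }
  for (k in seq_len(nStrandsPerSheet) - 1L) {
    sA <- if (anti) (-1)^k else 1            # sheet A strand sense at level k
    dirB <- sA * sigma                        # required sense in sheet B
    R <- if (dirB > 0 && !front) Id
         else if (dirB < 0 && front) Rz
         else if (dirB > 0 && front) Rx
         else Ry
    rows[[length(rows) + 1L]] <-
      place(R, c(0, sheetSep, stagger + k * rise),
            chains[nStrandsPerSheet + k + 1L])
  }
  atoms <- do.call(rbind, rows)

  set.seed(seed)
  tr <- random_rigid()
  xyz <- apply_rigid(as.matrix(atoms[, c("x", "y", "z")]), tr$R, tr$t)
  atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]

  list(structure = StructureModel(atoms,
         source = sprintf("synthetic class-%d zipper (%s)", classNumber,
                          sequence)),
       truth = list(within = at$within, polarity = at$polarity,
                    face = at$face, class = as.integer(classNumber)))
}

#' Synthetic stand-in assemblies for the deposited KRT8 segment structures
#'
#' Idealized reconstructions of the three deposited KRT8 fibril segment
#' structures, built from their described geometry rather than the
#' deposited coordinates (which are not bundled): \code{"7K3C"} -- the
#' wild-type SGMGGIT (residues 58-64) antiparallel class-7 zipper with
#' Gly61/Gly62 in the highly extended (near |180| degree) conformation;
#' \code{"7K3X"} -- the G62C mutant SGMGCIT parallel class-2 zipper, fully
#' pleated (Cys62 pleated); \code{"7K3Y"} -- the G55A mutant GGYAGAS
#' (residues 52-58) antiparallel class-6 zipper.  These are synthetic
#' models for offline geometric analysis, not crystallographic data.
#'
#' @param accession one of \code{"7K3C"}, \code{"7K3X"}, \code{"7K3Y"}
#' @return a \code{\linkS4class{StructureModel}}
#' @examples
#' classifyZipper(standinStructure("7K3X"))
#' @export
standinStructure <- function(accession) {
  accession <- toupper(accession)
  ext <- c(-170, 170)
  build <- function(cls, seqs, start, extended_at = integer(0), seed) {
    d <- idealBetaDihedrals(nchar(seqs))
    for (i in extended_at) d[i, c("phi", "psi")] <- ext
    z <- makeIdealZipperStructure(cls, seqs, seed = seed,
                                  startResno = start, dihedrals = d)
    st <- z$structure
    st@source <- sprintf("synthetic stand-in for %s (%s)", accession, seqs)
    st
  }
  switch(accession,
    "7K3C" = build(7L, "SGMGGIT", 58L, extended_at = c(4L, 5L), seed = 73L),
    "7K3X" = build(2L, "SGMGCIT", 58L, seed = 74L),
    "7K3Y" = build(6L, "GGYAGAS", 52L, extended_at = 1L, seed = 75L),
    stop("unknown accession: ", accession))
}
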