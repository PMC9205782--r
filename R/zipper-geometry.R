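# Geometric analysis of fibril structures: strand/sheet detection, polarity,
# steric-zipper class assignment (1-8), and backbone conformation labels.
#
# Coordinate conventions follow the classical steric-zipper taxonomy: a
# zipper is two mated beta-sheets, classified by three binary attributes --
# within-sheet strand polarity (parallel/antiparallel), face packing
# (face-to-face/face-to-back), and relative strand sense between the sheets
# (up-up/up-down).

# attribute triple -> class number (classical eight-class taxonomy)
ZIPPER_CLASS_TABLE <- data.frame(
  within = rep(c("parallel", "antiparallel"), each = 4L),
  polarity = rep(rep(c("up-up", "up-down"), each = 2L), 2L),
  face = rep(c("face-to-face", "face-to-back"), 4L),
  class = 1:8,
  stringsAsFactors = FALSE
)

# default phi/psi region boundaries (degrees) for conformation labels
CONFORMATION_REGIONS <- list(
  extended_min_abs = 155,                    # |phi| and |psi| at least this
  pleated_phi = c(-150, -90), pleated_psi = c(90, 150),
  kink_psi_abs = 60                          # |psi| below this, or phi > 0
)

#' @title StrandSet: strands, directions and sheet assignment
#' @slot strands data.frame with one row per polymer chain: \code{chain},
#'   \code{sheet} (integer label), \code{dx}, \code{dy}, \code{dz}
#'   (unit strand direction, first-to-last CA)
#' @export
setClass("StrandSet", representation(strands = "data.frame"))

setMethod("show", "StrandSet", function(object) {
  s <- object@strands
  cat(sprintf("StrandSet: %d strands in %d sheet(s)\n", nrow(s),
              length(unique(s$sheet))))
})

#' @title ZipperClassification: the three attributes and class number
#' @slot withinSheet \code{"parallel"} or \code{"antiparallel"}
#' @slot facePacking \code{"face-to-face"} or \code{"face-to-back"}
#' @slot sheetPolarity \code{"up-up"} or \code{"up-down"}
#' @slot classNumber integer 1-8
#' @export
setClass("ZipperClassification",
  representation(withinSheet = "character", facePacking = "character",
                 sheetPolarity = "character", classNumber = "integer"))

setMethod("show", "ZipperClassification", function(object) {
  cat(sprintf("Steric zipper class %d (%s, %s, %s)\n", object@classNumber,
              object@withinSheet, object@facePacking, object@sheetPolarity))
})

#' @keywords internal
chain_ca <- function(atoms, ch) {
  a <- atoms[atoms$record == "polymer" & atoms$chain == ch &
             atoms$atom == "CA", ]
  as.matrix(a[order(a$resno), c("x", "y", "z")])
}

#' @keywords internal
min_interchain_dist <- function(caA, caB) {
  d2 <- outer(rowSums(caA^2), rowSums(caB^2), "+") - 2 * caA %*% t(caB)
  sqrt(max(0, min(d2)))
}

#' Assign strands to sheets
#'
#' Each polymer chain gets a unit direction vector (first to last CA);
#' sheets are formed by single-linkage clustering of chains whose minimum
#' inter-chain CA-CA distance is at most 5.5 angstrom (the hydrogen-bonded
#' stacking distance regime).
#'
#' @param structure a \code{\linkS4class{StructureModel}}
#' @return a \code{\linkS4class{StrandSet}}
#' @export
assignStrands <- function(structure) {
  atoms <- structure@atoms
  chains <- structureChains(structure)
  if (length(chains) < 2L)
    stop("structure has a single polymer chain; expand the fibril assembly ",
         "(e.g. crystallographic neighbours) before strand assignment")
  cas <- lapply(chains, function(ch) chain_ca(atoms, ch))
  names(cas) <- chains
  dirs <- t(vapply(cas, function(m) {
    vunit(m[nrow(m), ] - m[1L, ])
  }, numeric(3)))
  nc <- length(chains)
  # union-find single linkage under the 5.5 A cutoff
  parent <- seq_len(nc)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nc - 1L)) for (j in seq(i + 1L, nc)) {
    if (min_interchain_dist(cas[[i]], cas[[j]]) <= 5.5) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(nc), find, 0L)
  sheet <- match(roots, unique(roots))
  methods::new("StrandSet",
               strands = data.frame(chain = chains, sheet = sheet,
                                    dx = dirs[, 1L], dy = dirs[, 2L],
                                    dz = dirs[, 3L],
                                    stringsAsFactors = FALSE))
}

#' Within-sheet strand orientation
#'
#' \code{"parallel"} if all hydrogen-bond-adjacent strand pairs in the sheet
#' run the same way (positive direction dot products), \code{"antiparallel"}
#' if all run opposite ways, otherwise \code{"other"}.
#'
#' @param structure a \code{\linkS4class{StructureModel}}
#' @param strandSet result of \code{\link{assignStrands}}
#' @param sheet sheet label (integer)
#' @return character scalar
#' @export
withinSheetOrientation <- function(structure, strandSet, sheet) {
  s <- strandSet@strands[strandSet@strands$sheet == sheet, ]
  if (nrow(s) < 2L) stop("sheet ", sheet, " has fewer than 2 strands")
  cas <- lapply(s$chain, function(ch) chain_ca(structure@atoms, ch))
  dots <- numeric(0)
  for (i in seq_len(nrow(s) - 1L)) for (j in seq(i + 1L, nrow(s))) {
    if (min_interchain_dist(cas[[i]], cas[[j]]) <= 5.5) {
      dots <- c(dots, sum(s[i, c("dx", "dy", "dz")] *
                          s[j, c("dx", "dy", "dz")]))
    }
  }
  if (length(dots) == 0L) return("other")
  if (all(dots > 0.2)) "parallel"
  else if (all(dots < -0.2)) "antiparallel"
  else "other"
}

# Which residue-index parity (odd/even) a sheet presents toward a direction.
# Projects CB-CA vectors onto the interface normal and takes the
# projection-weighted majority parity of positions pointing that way.
#' @keywords internal
sheet_face_parity <- function(atoms, chains, normal) {
  w_odd <- 0; w_even <- 0
  for (ch in chains) {
    a <- atoms[atoms$record == "polymer" & atoms$chain == ch, ]
    for (rn in unique(a$resno)) {
      r <- a[a$resno == rn, ]
      ca <- r[r$atom == "CA", c("x", "y", "z")]
      cb <- r[r$atom == "CB", c("x", "y", "z")]
      if (nrow(ca) != 1L || nrow(cb) != 1L) next
      proj <- sum((as.numeric(cb) - as.numeric(ca)) * normal)
      if (proj > 0) {
        if (rn %% 2L == 1L) w_odd <- w_odd + proj else w_even <- w_even + proj
      }
    }
  }
  if (w_odd == 0 && w_even == 0) return(NA_integer_)
  if (w_odd >= w_even) 1L else 0L
}

#' Classify a fibril structure into steric-zipper classes 1-8
#'
#' Detects the two mated sheets, computes the three binary attributes --
#' within-sheet polarity from adjacent-strand directions; face packing from
#' the residue parity each sheet presents at the interface (via CB
#' directions); sheet polarity from the strand sense of nearest-neighbour
#' strand pairs across the interface -- and maps them through the classical
#' class table.
#'
#' @param structure a \code{\linkS4class{StructureModel}} with two sheets
#'   of at least two strands each
#' @return a \code{\linkS4class{ZipperClassification}}
#' @export
classifyZipper <- function(structure) {
  ss <- assignStrands(structure)
  tab <- table(ss@strands$sheet)
  sheets <- as.integer(names(tab)[tab >= 2L])
  if (length(sheets) != 2L)
    stop("expected exactly two sheets with >= 2 strands, found ",
         length(sheets))
  atoms <- structure@atoms
  chA <- ss@strands$chain[ss@strands$sheet == sheets[1L]]
  chB <- ss@strands$chain[ss@strands$sheet == sheets[2L]]
  casA <- lapply(chA, function(ch) chain_ca(atoms, ch))
  casB <- lapply(chB, function(ch) chain_ca(atoms, ch))
  cenA <- colMeans(do.call(rbind, casA))
  cenB <- colMeans(do.call(rbind, casB))
  sep <- vnorm(cenB - cenA)
  if (sep > 12)
    stop("no detectable zipper interface (sheet separation ",
         round(sep, 1), " A)")

  wA <- withinSheetOrientation(structure, ss, sheets[1L])
  wB <- withinSheetOrientation(structure, ss, sheets[2L])
  if (wA == "other" || wB == "other" || wA != wB)
    stop("inconsistent within-sheet orientations: ", wA, " / ", wB)

  nAB <- vunit(cenB - cenA)
  pA <- sheet_face_parity(atoms, chA, nAB)
  pB <- sheet_face_parity(atoms, chB, -nAB)
  if (is.na(pA) || is.na(pB))
    stop("cannot determine face parity (no CB atoms at the interface)")
  face <- if (pA == pB) "face-to-face" else "face-to-back"

  # strand sense across the interface: match each strand in B to its
  # nearest strand (by centroid) in A and take the summed direction dot
  dirA <- ss@strands[ss@strands$sheet == sheets[1L], c("dx", "dy", "dz")]
  dirB <- ss@strands[ss@strands$sheet == sheets[2L], c("dx", "dy", "dz")]
  cA <- t(vapply(casA, colMeans, numeric(3)))
  cB <- t(vapply(casB, colMeans, numeric(3)))
  score <- 0
  for (j in seq_len(nrow(cB))) {
    i <- which.min(rowSums(sweep(cA, 2L, cB[j, ])^2))
    score <- score + sum(dirA[i, ] * dirB[j, ])
  }
  polarity <- if (score >= 0) "up-up" else "up-down"

  hit <- ZIPPER_CLASS_TABLE[ZIPPER_CLASS_TABLE$within == wA &
                            ZIPPER_CLASS_TABLE$face == face &
                            ZIPPER_CLASS_TABLE$polarity == polarity, ]
  methods::new("ZipperClassification", withinSheet = wA,
               facePacking = face, sheetPolarity = polarity,
               classNumber = as.integer(hit$class))
}

#' Label a backbone conformation from its phi/psi angles
#'
#' \code{"extended"} when both |phi| and |psi| reach 155 degrees (the
#' near-|180| flattened strand); \code{"pleated"} in the canonical
#' beta-pleat region (phi in [-150, -90], psi in [90, 150]);
#' \code{"kinked"} outside broad beta (positive phi or |psi| < 60);
#' \code{"other"} elsewhere.  Region bounds are package constants.
#'
#' @param phi,psi backbone torsions in degrees, in (-180, 180]
#' @return one of \code{"pleated"}, \code{"extended"}, \code{"kinked"},
#'   \code{"other"}
#' @export
classifyBackboneConformation <- function(phi, psi) {
  r <- CONFORMATION_REGIONS
  lab1 <- function(phi, psi) {
    if (is.na(phi) || is.na(psi)) return(NA_character_)
    if (abs(phi) >= r$extended_min_abs && abs(psi) >= r$extended_min_abs)
      return("extended")
    if (phi >= r$pleated_phi[1L] && phi <= r$pleated_phi[2L] &&
        psi >= r$pleated_psi[1L] && psi <= r$pleated_psi[2L])
      return("pleated")
    if (phi > 0 || abs(psi) < r$kink_psi_abs) return("kinked")
    "other"
  }
  mapply(lab1, phi, psi, USE.NAMES = FALSE)
}

#' Per-residue backbone conformation profile of one chain
#'
#' Measures phi/psi along the chain and labels interior residues with
#' \code{\link{classifyBackboneConformation}}; terminal residues (no phi or
#' no psi) are excluded, so the profile has \code{n - 2} entries for an
#' n-residue chain.  Residues with missing backbone atoms are labelled
#' \code{"other"} with a warning.
#'
#' @param structure a \code{\linkS4class{StructureModel}}
#' @param chain chain id
#' @return named character vector (names = residue numbers)
#' @export
pleatProfile <- function(structure, chain) {
  a <- structure@atoms[structure@atoms$record == "polymer" &
                       structure@atoms$chain == chain, ]
  resnos <- sort(unique(a$resno))
  if (length(resnos) < 3L) stop("chain ", chain, " has fewer than 3 residues")
  getat <- function(rn, nm) {
    r <- a[a$resno == rn & a$atom == nm, c("x", "y", "z")]
    if (nrow(r) != 1L) return(NULL)
    as.numeric(r)
  }
  inner <- resnos[-c(1L, length(resnos))]
  out <- character(length(inner))
  names(out) <- inner
  for (k in seq_along(inner)) {
    rn <- inner[k]
    Cp <- getat(rn - 1L, "C")
    N <- getat(rn, "N"); CA <- getat(rn, "CA"); C <- getat(rn, "C")
    Nn <- getat(rn + 1L, "N")
    if (is.null(Cp) || is.null(N) || is.null(CA) || is.null(C) ||
        is.null(Nn)) {
      warning("missing backbone atoms at residue ", rn, " of chain ", chain,
              "; labelled 'other'")
      out[k] <- "other"
      next
    }
    phi <- dihedral_angle(Cp, N, CA, C)
    psi <- dihedral_angle(N, CA, C, Nn)
    out[k] <- classifyBackboneConformation(phi, psi)
  }
  out
}
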