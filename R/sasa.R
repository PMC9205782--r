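# Numerical solvent-accessible surface area (Shrake-Rupley sphere-point
# sampling) and the buried interface area between the two sheets of a
# steric zipper.

# van der Waals radii for SASA (angstrom), by element
SASA_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Solvent-accessible surface area by sphere-point sampling
#'
#' Shrake-Rupley numerical SASA: each atom is covered with a deterministic
#' quasi-uniform point lattice at radius (vdW + probe); points inside any
#' neighbouring atom's probe-expanded sphere are occluded.
#'
#' @param xyz n x 3 coordinate matrix
#' @param elements length-n element symbols (C, N, O, S)
#' @param probe probe radius in angstrom (water: 1.4)
#' @param nPoints sphere points per atom (>= 960 recommended)
#' @return numeric vector of per-atom areas in square angstrom
#' @export
shrakeRupleySasa <- function(xyz, elements, probe = 1.4, nPoints = 960L) {
  n <- nrow(xyz)
  rad <- SASA_RADII[elements]
  rad[is.na(rad)] <- 1.7
  rs <- rad + probe
  pts <- fibonacci_sphere(nPoints)
  out <- numeric(n)
  # neighbour lists under the maximal interaction distance
  maxr <- max(rs)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 < (rs[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (rs[i] + rs[nb])^2]
    sp <- sweep(pts * rs[i], 2L, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, nPoints)
      for (j in nb) {
        if (!any(free)) break
        dj2 <- rowSums(sweep(sp[free, , drop = FALSE], 2L, xyz[j, ])^2)
        free[free] <- dj2 > rs[j]^2
      }
      frac <- sum(free) / nPoints
    } else frac <- 1
    out[i] <- 4 * pi * rs[i]^2 * frac
  }
  out
}

#' Buried interface area between the two sheets of a zipper
#'
#' Computes SASA of each sheet alone and of the complex, and returns
#' \code{(SASA_A + SASA_B - SASA_complex) / 2} normalized per strand layer
#' (the number of strands in a sheet).  Zero when the sheets are out of
#' contact range.
#'
#' @param structure a \code{\linkS4class{StructureModel}}
#' @param probe probe radius (angstrom)
#' @param nPoints sphere points per atom
#' @param includeLigands count ligand atoms as part of the surface
#' @return buried area in square angstrom per strand layer
#' @export
buriedInterfaceArea <- function(structure, probe = 1.4, nPoints = 960L,
                                includeLigands = FALSE) {
  ss <- assignStrands(structure)
  tab <- table(ss@strands$sheet)
  sheets <- as.integer(names(tab)[tab >= 2L])
  if (length(sheets) != 2L)
    stop("expected two sheets with >= 2 strands, found ", length(sheets))
  atoms <- structure@atoms
  keep <- atoms$record == "polymer" |
    (includeLigands & atoms$record == "ligand")
  atoms <- atoms[keep, ]
  chA <- ss@strands$chain[ss@strands$sheet == sheets[1L]]
  chB <- ss@strands$chain[ss@strands$sheet == sheets[2L]]
  inA <- atoms$chain %in% chA
  inB <- atoms$chain %in% chB
  sasa_of <- function(sel) {
    sub <- atoms[sel, ]
    sum(shrakeRupleySasa(as.matrix(sub[, c("x", "y", "z")]), sub$element,
                         probe, nPoints))
  }
  buried <- sasa_of(inA) + sasa_of(inB) - sasa_of(inA | inB)
  layers <- max(length(chA), length(chB))
  max(0, buried / 2 / layers)
}
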