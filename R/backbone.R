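# Fixed backbone templates and fibril expansion.
#
# A BackboneTemplate is a per-residue (phi, psi, omega) table realized as
# ideal-geometry backbone coordinates (N, CA, C, O and a CB stub), oriented
# in a canonical frame: strand axis along +x, fibril (stacking) axis along
# +z, sheet normal along +y.  A FibrilAssembly is a set of rigid-body copies
# of the template strand: n strands stacked per sheet, one or two sheets.

BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
BOND_CA_CB <- 1.530
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.1
ANGLE_C_CA_CB <- 110.1
IMPROPER_N_C_CA_CB <- 122.6  # L-amino-acid chirality

#' @title BackboneTemplate: a fixed fibril backbone defined by dihedrals
#'
#' @description Holds the per-residue (phi, psi, omega) table of a template
#' strand together with its fibril parameters: the axial rise between
#' stacked strands, the inter-sheet separation, the axial stagger of the
#' mating sheet, and the within-sheet stacking mode.  The realized canonical
#' backbone coordinates are stored in the \code{coords} slot.
#'
#' @slot name template identifier, e.g. \code{"LARKS_STGGYS"}
#' @slot category \code{"LARKS"} (kinked) or \code{"zipper"} (pleated)
#' @slot dihedrals n x 3 matrix, columns \code{phi}, \code{psi},
#'   \code{omega} (degrees); \code{phi[1]} and \code{omega[1]} are unused
#' @slot rise axial translation per stacked strand (angstrom)
#' @slot sheetSep distance between the two sheets (angstrom)
#' @slot sheetStagger axial offset of the mating sheet (angstrom)
#' @slot packing \code{"parallel"} or \code{"antiparallel"} in-sheet stacking
#' @slot coords list, one n-row named coordinate matrix
#'   (\code{N, CA, C, O, CB}) per residue, canonical frame
#' @export
setClass("BackboneTemplate",
  representation(name = "character", category = "character",
                 dihedrals = "matrix", rise = "numeric",
                 sheetSep = "numeric", sheetStagger = "numeric",
                 packing = "character", coords = "list"))

setValidity("BackboneTemplate", function(object) {
  msg <- character(0)
  n <- nrow(object@dihedrals)
  if (n < 3L) msg <- c(msg, "template must have at least 3 residues")
  if (!object@category %in% c("LARKS", "zipper"))
    msg <- c(msg, "category must be 'LARKS' or 'zipper'")
  om <- object@dihedrals[-1L, "omega"]
  dev <- pmin(abs(om - 180), abs(om + 180))
  if (any(dev > 20))
    msg <- c(msg, "all omega angles must be within 20 degrees of trans (180)")
  if (object@rise < 4 || object@rise > 10)
    msg <- c(msg, "rise must lie in [4, 10] angstrom")
  if (length(object@coords) != n)
    msg <- c(msg, "coords must hold one matrix per residue")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BackboneTemplate", function(object) {
  cat(sprintf("BackboneTemplate '%s' (%s): %d residues, rise %.2f A, sheet sep %.2f A\n",
              object@name, object@category, nrow(object@dihedrals),
              object@rise, object@sheetSep))
})

#' Number of residues in a template strand
#' @param x a \code{BackboneTemplate}
#' @export
templateLength <- function(x) nrow(x@dihedrals)

#' Build ideal-geometry backbone coordinates from a dihedral table
#'
#' Realizes a peptide backbone (N, CA, C, O per residue, plus a CB stub
#' placed with L-amino-acid chirality) from per-residue (phi, psi, omega)
#' torsions using fixed ideal bond lengths and angles.  \code{phi} of the
#' first residue and \code{omega} of the first residue are unused.
#' Re-measuring phi/psi from the built coordinates reproduces the input
#' table (the construction is exact forward kinematics).
#'
#' @param dihedrals numeric n x 3 matrix with columns \code{phi},
#'   \code{psi}, \code{omega} in degrees
#' @param sequence_length expected residue count; must equal
#'   \code{nrow(dihedrals)}
#' @return list of n named 5 x 3 coordinate matrices (rows
#'   \code{N, CA, C, O, CB})
#' @examples
#' bb <- buildBackbone(idealBetaDihedrals(6), 6)
#' measurePhiPsi(bb)
#' @export
buildBackbone <- function(dihedrals, sequence_length = nrow(dihedrals)) {
  if (is.null(colnames(dihedrals)))
    colnames(dihedrals) <- c("phi", "psi", "omega")
  n <- nrow(dihedrals)
  if (n != sequence_length)
    stop("dihedral table has ", n, " rows but sequence_length is ",
         sequence_length)
  res <- vector("list", n)
  # first residue in an arbitrary frame; canonical orientation comes later
  N <- c(0, 0, 0)
  CA <- c(BOND_N_CA, 0, 0)
  ang <- ANGLE_N_CA_C * pi / 180
  C <- CA + c(-BOND_CA_C * cos(ang), BOND_CA_C * sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      prev <- res[[i - 1L]]
      N <- place_atom(prev["N", ], prev["CA", ], prev["C", ],
                      BOND_C_N, ANGLE_CA_C_N, dihedrals[i - 1L, "psi"])
      CA <- place_atom(prev["CA", ], prev["C", ], N,
                       BOND_N_CA, ANGLE_C_N_CA, dihedrals[i, "omega"])
      C <- place_atom(prev["C", ], N, CA,
                      BOND_CA_C, ANGLE_N_CA_C, dihedrals[i, "phi"])
    }
    O <- place_atom(N, CA, C, BOND_C_O, ANGLE_CA_C_O,
                    dihedrals[i, "psi"] + 180)
    CB <- place_atom(N, C, CA, BOND_CA_CB, ANGLE_C_CA_CB,
                     IMPROPER_N_C_CA_CB)
    m <- rbind(N = N, CA = CA, C = C, O = O, CB = CB)
    colnames(m) <- c("x", "y", "z")
    res[[i]] <- m
  }
  orient_backbone(res)
}

# Canonical frame: CA1->CAn along +x; +z from the alternating carbonyl
# directions (the inter-strand hydrogen-bonding/stacking axis); CA centroid
# at the origin.
#' @keywords internal
orient_backbone <- function(res) {
  n <- length(res)
  cas <- t(vapply(res, function(m) m["CA", ], numeric(3)))
  xax <- vunit(cas[n, ] - cas[1, ])
  co <- vapply(seq_len(n), function(i)
    (res[[i]]["O", ] - res[[i]]["C", ]) * (-1)^i, numeric(3))
  v <- rowMeans(co)
  v <- v - sum(v * xax) * xax
  zax <- vunit(v)
  yax <- vcross(zax, xax)
  R <- rbind(xax, yax, zax)          # rows: new basis in old coordinates
  ctr <- colMeans(cas)
  lapply(res, function(m) {
    out <- sweep(m, 2L, ctr) %*% t(R)
    colnames(out) <- c("x", "y", "z")
    out
  })
}

#' Measure backbone phi/psi angles from built coordinates
#'
#' @param backbone list of per-residue coordinate matrices as returned by
#'   \code{\link{buildBackbone}} (rows \code{N, CA, C} required)
#' @return n x 2 matrix of phi and psi in degrees (\code{NA} where
#'   undefined: phi of the first residue, psi of the last)
#' @export
measurePhiPsi <- function(backbone) {
  n <- length(backbone)
  out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("phi", "psi")))
  for (i in seq_len(n)) {
    r <- backbone[[i]]
    if (i > 1L) {
      p <- backbone[[i - 1L]]
      out[i, "phi"] <- dihedral_angle(p["C", ], r["N", ], r["CA", ], r["C", ])
    }
    if (i < n) {
      nx <- backbone[[i + 1L]]
      out[i, "psi"] <- dihedral_angle(r["N", ], r["CA", ], r["C", ], nx["N", ])
    }
  }
  out
}

#' Ideal pleated-beta dihedral table
#' @param n number of residues
#' @param phi,psi,omega backbone torsions applied uniformly (degrees)
#' @return n x 3 matrix usable with \code{\link{buildBackbone}}
#' @export
idealBetaDihedrals <- function(n, phi = -120, psi = 120, omega = 180) {
  matrix(c(rep(phi, n), rep(psi, n), rep(omega, n)), ncol = 3L,
         dimnames = list(NULL, c("phi", "psi", "omega")))
}

#' Construct a BackboneTemplate
#'
#' @param name template identifier
#' @param category \code{"LARKS"} or \code{"zipper"}
#' @param dihedrals n x 3 phi/psi/omega table (degrees)
#' @param rise axial rise per stacked strand (angstrom)
#' @param sheetSep inter-sheet separation (angstrom)
#' @param sheetStagger axial stagger of the mating sheet (angstrom)
#' @param packing within-sheet stacking, \code{"parallel"} or
#'   \code{"antiparallel"}
#' @return a \code{\linkS4class{BackboneTemplate}}
#' @export
BackboneTemplate <- function(name, category, dihedrals, rise = 4.8,
                             sheetSep = 10, sheetStagger = rise / 2,
                             packing = "parallel") {
  if (is.null(colnames(dihedrals)))
    colnames(dihedrals) <- c("phi", "psi", "omega")
  coords <- buildBackbone(dihedrals)
  methods::new("BackboneTemplate", name = name, category = category,
               dihedrals = dihedrals, rise = rise, sheetSep = sheetSep,
               sheetStagger = sheetStagger, packing = packing,
               coords = coords)
}

#' Built-in threading templates
#'
#' Returns the four fixed backbones used by the screen: three kinked LARKS
#' templates, named after the segments whose fibril structures motivated
#' them (STGGYS, SYSGYS, GYNGFG), and one pleated steric-zipper template.
#' The LARKS tables are idealized kinked-beta backbones: beta-like residues
#' with a glycine-type kink (positive phi, near-zero psi) at position 4.
#' The zipper template is an ideal parallel in-register pleated strand.
#'
#' @return named list of four \code{\linkS4class{BackboneTemplate}} objects
#' @examples
#' names(builtinTemplates())
#' @export
builtinTemplates <- function() {
  larks <- function(name, kink_pos, kink, reentry) {
    d <- idealBetaDihedrals(6, phi = -125, psi = 130)
    d[kink_pos, c("phi", "psi")] <- kink
    d[kink_pos + 1L, c("phi", "psi")] <- reentry
    BackboneTemplate(name, "LARKS", d, rise = 4.8, sheetSep = 10,
                     sheetStagger = 2.4)
  }
  # The kinked templates place a glycine-type kink at two registers
  # (positions 3 and 2) so that a window is accommodated whenever either
  # register aligns a small residue with the kink.  Kink and re-entry
  # torsions were tuned so each template's namesake segment threads onto
  # its own backbone with low energy (no forced clash between aromatic
  # side chains and their stacked strand images).
  list(
    LARKS_STGGYS = larks("LARKS_STGGYS", 3L, c(75, 50), c(-130, 135)),
    LARKS_SYSGYS = larks("LARKS_SYSGYS", 3L, c(87.5, 30), c(-90, 105)),
    LARKS_GYNGFG = larks("LARKS_GYNGFG", 2L, c(87.5, 30), c(-90, 105)),
    ZIPPER_P1 = BackboneTemplate("ZIPPER_P1", "zipper",
                                 idealBetaDihedrals(6), rise = 4.8,
                                 sheetSep = 9.0, sheetStagger = 2.4)
  )
}

#' @title FibrilAssembly: rigid-body strand copies of a template
#'
#' @description The fibril context used for threading: every strand is an
#' exact rigid image of the template strand, labelled by sheet (A or B) and
#' stack index.
#'
#' @slot template the source \code{\linkS4class{BackboneTemplate}}
#' @slot strandInfo data.frame with columns \code{strand}, \code{sheet},
#'   \code{stack}, \code{central} (logical: the query-centred strand)
#' @slot transforms list of \code{list(R, t)} rigid transforms, one per
#'   strand, mapping template-frame coordinates into the assembly
#' @export
setClass("FibrilAssembly",
  representation(template = "BackboneTemplate", strandInfo = "data.frame",
                 transforms = "list"))

setMethod("show", "FibrilAssembly", function(object) {
  cat(sprintf("FibrilAssembly of '%s': %d strands (%d sheet%s)\n",
              object@template@name, nrow(object@strandInfo),
              length(unique(object@strandInfo$sheet)),
              if (length(unique(object@strandInfo$sheet)) > 1L) "s" else ""))
})

#' Expand a template strand into its fibril context
#'
#' Builds \code{nSheets * nStrandsPerSheet} exact rigid copies of the
#' template strand: stacked along the fibril axis with the template's rise
#' (alternating 180-degree flips about the sheet normal when the template's
#' packing is antiparallel), with the second sheet generated by a
#' 180-degree rotation about the fibril axis followed by the template's
#' inter-sheet offset and axial stagger.
#'
#' @param template a \code{\linkS4class{BackboneTemplate}}
#' @param nStrandsPerSheet strands per sheet (>= 1)
#' @param nSheets 1 or 2
#' @return a \code{\linkS4class{FibrilAssembly}}
#' @examples
#' fa <- expandFibril(builtinTemplates()$ZIPPER_P1, 5, 2)
#' fa
#' @export
expandFibril <- function(template, nStrandsPerSheet, nSheets = 2) {
  stopifnot(nStrandsPerSheet >= 1, nSheets %in% c(1L, 2L))
  # re-orient into the canonical strand frame so that stacking (+z) and the
  # inter-sheet offset (+y) are meaningful regardless of how the template's
  # realized coordinates have been rigidly moved
  template@coords <- orient_backbone(template@coords)
  rise <- template@rise
  info <- list(); trs <- list()
  central_stack <- (nStrandsPerSheet - 1L) %/% 2L
  id <- 0L
  for (sheet in c("A", "B")[seq_len(nSheets)]) {
    for (k in seq_len(nStrandsPerSheet) - 1L) {
      id <- id + 1L
      R <- diag(3)
      t <- c(0, 0, k * rise)
      if (template@packing == "antiparallel" && k %% 2L == 1L)
        R <- rotation_about_axis(c(0, 1, 0), 180) %*% R
      if (sheet == "B") {
        R <- rotation_about_axis(c(0, 0, 1), 180) %*% R
        t <- c(0, template@sheetSep, template@sheetStagger + k * rise)
      }
      info[[id]] <- data.frame(strand = id, sheet = sheet, stack = k,
                               central = (sheet == "A" && k == central_stack))
      trs[[id]] <- list(R = R, t = t)
    }
  }
  methods::new("FibrilAssembly", template = template,
               strandInfo = do.call(rbind, info), transforms = trs)
}

#' Backbone coordinates of every strand in an assembly
#'
#' @param assembly a \code{\linkS4class{FibrilAssembly}}
#' @return list (one element per strand) of lists of per-residue 5 x 3
#'   coordinate matrices
#' @export
assemblyBackbones <- function(assembly) {
  tmpl <- assembly@template@coords
  lapply(assembly@transforms, function(tr) {
    lapply(tmpl, function(m) {
      out <- apply_rigid(m, tr$R, tr$t)
      rownames(out) <- rownames(m)
      colnames(out) <- c("x", "y", "z")
      out
    })
  })
}
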