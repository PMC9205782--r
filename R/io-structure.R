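# Coordinate-file handling.  StructureModel is a thin S4 container around an
# atom table; PDB reading and writing go through bio3d.

STANDARD_AA3 <- unname(AA3)
WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' @title StructureModel: an atomic structure with record classes
#' @description Atom table of a (fibril) structure.  Each atom carries a
#' chain id, residue number and name, atom name, element, coordinates,
#' occupancy, and a record class (\code{polymer}, \code{ligand} or
#' \code{water}).  Modified residues read from PDB input are mapped to
#' their parent standard residue.
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resname}, \code{atom}, \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{occupancy}, \code{record}
#' @slot source provenance string (file path or generator description)
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", source = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z",
            "occupancy", "record")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("coordinates must be finite")
  poly <- a[a$record == "polymer", ]
  for (ch in unique(poly$chain)) {
    r <- rle(poly$resno[poly$chain == ch])$values
    if (any(diff(r) <= 0))
      return(paste0("polymer residues in chain ", ch,
                    " are not strictly ordered"))
  }
  TRUE
})

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  poly <- a[a$record == "polymer", ]
  cat(sprintf("StructureModel: %d atoms (%d polymer, %d chains); %s\n",
              nrow(a), nrow(poly), length(unique(poly$chain)),
              object@source))
})

#' Atom table of a StructureModel
#' @param x a \code{StructureModel}
#' @export
structureAtoms <- function(x) x@atoms

#' Polymer chain ids of a StructureModel
#' @param x a \code{StructureModel}
#' @export
structureChains <- function(x) {
  unique(x@atoms$chain[x@atoms$record == "polymer"])
}

#' One-letter polymer sequence of one chain
#' @param x a \code{StructureModel}
#' @param chain chain id
#' @export
chainSequence <- function(x, chain) {
  a <- x@atoms[x@atoms$record == "polymer" & x@atoms$chain == chain, ]
  res <- a[!duplicated(a$resno), ]
  paste(AA3_TO_1[res$resname], collapse = "")
}

#' Construct a StructureModel from an atom table
#' @param atoms data.frame (see the class description)
#' @param source provenance string
#' @return a \code{StructureModel}
#' @export
StructureModel <- function(atoms, source = "constructed") {
  rownames(atoms) <- NULL
  methods::new("StructureModel", atoms = atoms, source = source)
}

#' Read a PDB coordinate file
#'
#' Atoms are classified as \code{polymer} (standard amino acids, plus
#' modified residues such as MSE mapped to their parent), \code{water}, or
#' \code{ligand}.  Fails if the file contains no polymer atoms.
#'
#' @param path PDB file
#' @return a \code{\linkS4class{StructureModel}}
#' @export
readStructurePdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  resname <- toupper(a$resid)
  mapped <- MODIFIED_PARENT[resname]
  resname[!is.na(mapped)] <- mapped[!is.na(mapped)]
  record <- ifelse(resname %in% STANDARD_AA3, "polymer",
                   ifelse(resname %in% WATER_NAMES, "water", "ligand"))
  el <- a$elesy
  if (is.null(el) || all(is.na(el) | el == ""))
    el <- vapply(a$elety, element_of, "")
  atoms <- data.frame(chain = ifelse(is.na(a$chain) | a$chain == "",
                                     "A", a$chain),
                      resno = a$resno, resname = resname, atom = a$elety,
                      element = toupper(trimws(el)),
                      x = a$x, y = a$y, z = a$z,
                      occupancy = ifelse(is.na(a$o), 1, a$o),
                      record = record, stringsAsFactors = FALSE)
  if (!any(atoms$record == "polymer"))
    stop("no polymer atoms in ", path)
  ord <- order(match(atoms$record, c("polymer", "ligand", "water")),
               atoms$chain, atoms$resno)
  StructureModel(atoms[ord, , drop = FALSE], source = path)
}

#' Write a StructureModel to a PDB file
#'
#' Round-trip read -> write -> read preserves atom count, names, and
#' coordinates to three decimals (PDB precision).
#'
#' @param model a \code{\linkS4class{StructureModel}}
#' @param path output file
#' @return invisibly, the path
#' @export
writeStructurePdb <- function(model, path) {
  a <- model@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$record == "polymer", "ATOM", "HETATM"),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   elety = a$atom, o = a$occupancy,
                   b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

#' Convert a threaded model to a StructureModel
#'
#' Strand copies become chains A, B, C, ... in strand order.
#'
#' @param model a \code{\linkS4class{ThreadedModel}}
#' @return a \code{\linkS4class{StructureModel}}
#' @export
threadedModelToStructure <- function(model) {
  a <- model@atoms
  chains <- c(LETTERS, letters)[a$strand]
  atoms <- data.frame(chain = chains, resno = a$resno,
                      resname = unname(AA3[a$resname]), atom = a$atom,
                      element = a$element, x = a$x, y = a$y, z = a$z,
                      occupancy = 1, record = "polymer",
                      stringsAsFactors = FALSE)
  StructureModel(atoms, source = sprintf("threaded %s on %s",
                                         model@sequence,
                                         model@templateName))
}
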