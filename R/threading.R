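# Fixed-backbone threading: graft a query sequence onto every strand of a
# fibril assembly, place side chains by symmetry-coupled discrete rotamer
# search, and score the model with a decomposed packing energy.
#
# The energy is an original four-term function in arbitrary units
# (soft steric repulsion, capped packing attraction, pairwise desolvation,
# geometric hydrogen bonds); it makes no attempt to reproduce any published
# force field's magnitudes -- only orderings and thresholded calls are used
# downstream.

PRO_STRAIN <- 8      # backbone-strain penalty (E_rep units) for proline at a
                     # template position whose phi lies outside [-100, -30]

#' Default energy-term weights
#' @return named numeric vector with elements \code{rep}, \code{att},
#'   \code{solv}, \code{hb}
#' @export
defaultEnergyWeights <- function() {
  c(rep = 1, att = 1, solv = 0.5, hb = 1)
}

#' @title EnergyBreakdown: decomposed threading energy
#' @description Total threading energy and its four raw components; the
#' identity \code{total = w_rep*rep + w_att*att + w_solv*solv + w_hb*hb}
#' holds exactly.  Units are arbitrary.
#' @slot total weighted total energy
#' @slot rep steric repulsion (raw, >= 0)
#' @slot att packing attraction (raw, <= 0)
#' @slot solv desolvation (raw; sign follows buried polarity)
#' @slot hb hydrogen-bond reward (raw, <= 0)
#' @slot weights the weight vector applied
#' @export
setClass("EnergyBreakdown",
  representation(total = "numeric", rep = "numeric", att = "numeric",
                 solv = "numeric", hb = "numeric", weights = "numeric"))

setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf("EnergyBreakdown: total %.3f (rep %.3f, att %.3f, solv %.3f, hb %.3f)\n",
              object@total, object@rep, object@att, object@solv, object@hb))
})

#' Total energy of a breakdown or threaded model
#' @param x an \code{EnergyBreakdown} or \code{ThreadedModel}
#' @export
totalEnergy <- function(x) {
  if (methods::is(x, "ThreadedModel")) x <- x@energy
  x@total
}

#' Raw energy terms of a breakdown as a named vector
#' @param x an \code{EnergyBreakdown} or \code{ThreadedModel}
#' @export
energyTerms <- function(x) {
  if (methods::is(x, "ThreadedModel")) x <- x@energy
  c(rep = x@rep, att = x@att, solv = x@solv, hb = x@hb)
}

#' @title ThreadedModel: a sequence threaded onto a fibril template
#' @description All-atom model of a query window grafted onto every strand
#' of a fibril assembly (homotypic in-register stacking), with one shared
#' rotamer choice per position and an \code{\linkS4class{EnergyBreakdown}}.
#' @slot templateName name of the source template
#' @slot sequence the threaded window (one-letter codes)
#' @slot assembly the \code{\linkS4class{FibrilAssembly}} context
#' @slot rotamers chosen rotamer index per position (shared by all strands)
#' @slot atoms data.frame of all heavy atoms: \code{strand}, \code{sheet},
#'   \code{resno}, \code{resname}, \code{atom}, \code{element},
#'   \code{x}, \code{y}, \code{z}
#' @slot energy the \code{\linkS4class{EnergyBreakdown}}
#' @slot packed logical: has rotamer optimisation been run
#' @slot changedCycles number of packing sweeps that changed a rotamer
#' @slot converged logical: packing reached a sweep with no change
#' @slot energyPath total energy after each accepted rotamer change
#' @export
setClass("ThreadedModel",
  representation(templateName = "character", sequence = "character",
                 assembly = "FibrilAssembly", rotamers = "integer",
                 atoms = "data.frame", energy = "EnergyBreakdown",
                 packed = "logical", changedCycles = "integer",
                 converged = "logical", energyPath = "numeric"))

setMethod("show", "ThreadedModel", function(object) {
  cat(sprintf("ThreadedModel '%s' on %s: E_total %.3f (%s)\n",
              object@sequence, object@templateName, object@energy@total,
              if (object@packed) "packed" else "unpacked"))
})

# ---- atom parameter assembly ------------------------------------------------

# acceptor -> bonded parent atom name, for the hydrogen-bond angle test
HB_PARENT <- c(O = "C", OD1 = "CG", OD2 = "CG", OE1 = "CD", OE2 = "CD",
               OG = "CB", OG1 = "CB", OH = "CZ", ND1 = "CG", NE2 = "CD2")

#' @keywords internal
atom_namecode <- function(name) {
  match(name, c("N", "CA", "C", "O", "CB"), nomatch = 0L)
}

#' @keywords internal
empty_atomset <- function() {
  list(x = numeric(0), y = numeric(0), z = numeric(0),
       radius = numeric(0), eps = numeric(0), solv = numeric(0),
       px = numeric(0), py = numeric(0), pz = numeric(0),
       donor = logical(0), acceptor = logical(0), has_parent = logical(0),
       strand = integer(0), resno = integer(0), namecode = integer(0),
       name = character(0), resname = character(0))
}

# Build the C++-ready atom set for a block of atoms of one residue type.
# coords: named matrix (rows = atom names); aa1: one-letter code.
#' @keywords internal
make_atomset <- function(coords, aa1, resno, strand) {
  nm <- rownames(coords)
  el <- vapply(nm, element_of, "")
  pi_ <- match(el, ELEMENT_PARAMS$element)
  donor <- nm %in% HB_DONOR_NAMES
  if (aa1 == "P") donor[nm == "N"] <- FALSE       # proline N carries no H
  acceptor <- nm %in% HB_ACCEPTOR_NAMES
  if (aa1 != "H") acceptor[nm %in% c("ND1", "NE2")] <- FALSE
  parent_nm <- HB_PARENT[nm]
  has_parent <- acceptor & !is.na(parent_nm) & parent_nm %in% nm
  px <- py <- pz <- rep(0, length(nm))
  if (any(has_parent)) {
    idx <- match(parent_nm[has_parent], nm)
    px[has_parent] <- coords[idx, 1L]
    py[has_parent] <- coords[idx, 2L]
    pz[has_parent] <- coords[idx, 3L]
  }
  list(x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
       radius = ELEMENT_PARAMS$radius[pi_], eps = ELEMENT_PARAMS$eps[pi_],
       solv = unname(atom_solv(aa1, nm, el)), px = px, py = py, pz = pz,
       donor = donor, acceptor = acceptor, has_parent = has_parent,
       strand = rep(as.integer(strand), length(nm)),
       resno = rep(as.integer(resno), length(nm)),
       namecode = vapply(nm, atom_namecode, 0L),
       name = nm, resname = rep(aa1, length(nm)))
}

#' @keywords internal
cat_atomsets <- function(sets) {
  sets <- Filter(function(s) length(s$x) > 0L, sets)
  if (length(sets) == 0L) return(empty_atomset())
  if (length(sets) == 1L) return(sets[[1L]])
  out <- lapply(names(sets[[1L]]), function(f)
    do.call(c, lapply(sets, `[[`, f)))
  names(out) <- names(sets[[1L]])
  out
}

#' @keywords internal
transform_atomset <- function(set, R, t, strand) {
  n <- length(set$x)
  if (n == 0L) return(set)
  xyz <- apply_rigid(cbind(set$x, set$y, set$z), R, t)
  pxyz <- apply_rigid(cbind(set$px, set$py, set$pz), R, t)
  set$x <- xyz[, 1L]; set$y <- xyz[, 2L]; set$z <- xyz[, 3L]
  set$px <- pxyz[, 1L]; set$py <- pxyz[, 2L]; set$pz <- pxyz[, 3L]
  set$strand <- rep(as.integer(strand), n)
  set
}

# Place the side-chain atoms of residue aa1 beyond CB, given backbone
# coordinates in the template frame and a chi vector.  Returns a named
# coordinate matrix (possibly 0-row).
#' @keywords internal
build_sidechain <- function(aa1, chi, bbN, bbCA, bbC, bbCB) {
  top <- SIDECHAIN_TOPOLOGY[[AA3[[aa1]]]]
  if (length(top) == 0L) {
    return(matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("x", "y", "z"))))
  }
  pos <- list(N = bbN, CA = bbCA, C = bbC, CB = bbCB)
  out <- matrix(0, length(top), 3L,
                dimnames = list(vapply(top, `[[`, "", "name"),
                                c("x", "y", "z")))
  for (i in seq_along(top)) {
    at <- top[[i]]
    tor <- if (at$chi > 0L) chi[at$chi] + at$offset else at$offset
    p <- place_atom(pos[[at$a]], pos[[at$b]], pos[[at$c]],
                    at$bond, at$angle, tor)
    pos[[at$name]] <- p
    out[i, ] <- p
  }
  out
}

# ---- engine -----------------------------------------------------------------

# Precomputes, for a (assembly, sequence) pair: the fixed atom set
# (backbone + CB, all strands) and per-position per-rotamer movable blocks
# (side-chain atoms beyond CB, replicated across all strands).
#' @keywords internal
build_engine <- function(assembly, sequence, lib = rotamerLibrary()) {
  tmpl <- assembly@template
  k <- templateLength(tmpl)
  seqv <- strsplit(sequence, "")[[1L]]
  if (length(seqv) != k)
    stop("sequence length ", length(seqv),
         " does not match template length ", k)
  if (any(seqv == "X"))
    stop("cannot thread 'X' (unknown residue) onto a template")
  bad <- setdiff(seqv, AA1)
  if (length(bad))
    stop("non-standard residue letter(s): ", paste(bad, collapse = ", "))

  trs <- assembly@transforms
  nstr <- length(trs)
  coords <- tmpl@coords

  fixed <- list(); blocks <- vector("list", k)
  for (i in seq_len(k)) {
    aa <- seqv[i]
    cm <- coords[[i]]
    bb_names <- if (aa == "G") c("N", "CA", "C", "O") else
      c("N", "CA", "C", "O", "CB")
    base <- make_atomset(cm[bb_names, , drop = FALSE], aa, i, 0L)
    for (s in seq_len(nstr)) {
      fixed[[length(fixed) + 1L]] <-
        transform_atomset(base, trs[[s]]$R, trs[[s]]$t, s)
    }
    rots <- lib[[aa]]
    blocks[[i]] <- lapply(rots, function(chi) {
      sc <- build_sidechain(aa, chi, cm["N", ], cm["CA", ], cm["C", ],
                            cm["CB", ])
      if (nrow(sc) == 0L) return(empty_atomset())
      bset <- make_atomset(sc, aa, i, 0L)
      cat_atomsets(lapply(seq_len(nstr), function(s)
        transform_atomset(bset, trs[[s]]$R, trs[[s]]$t, s)))
    })
  }
  phis <- tmpl@dihedrals[, "phi"]
  strained <- sum(seqv == "P" & seq_len(k) > 1L &
                  (phis < -100 | phis > -30))
  list(fixed = cat_atomsets(fixed), blocks = blocks, seq = seqv, k = k,
       prostrain = strained * PRO_STRAIN, template = tmpl, nstr = nstr)
}

#' @keywords internal
raw_energy_between <- function(a, b) {
  if (length(a$x) == 0L || length(b$x) == 0L)
    return(c(rep = 0, att = 0, solv = 0, hb = 0))
  .energy_between(a, b)
}

#' @keywords internal
raw_energy_within <- function(a) {
  if (length(a$x) < 2L) return(c(rep = 0, att = 0, solv = 0, hb = 0))
  .energy_within(a)
}

#' @keywords internal
weighted_total <- function(raw, weights) {
  sum(weights[c("rep", "att", "solv", "hb")] *
      raw[c("rep", "att", "solv", "hb")])
}

# Full raw components of the current rotamer state.
#' @keywords internal
engine_full_raw <- function(eng, rot) {
  all <- cat_atomsets(c(list(eng$fixed),
                        lapply(seq_len(eng$k), function(p)
                          eng$blocks[[p]][[rot[p]]])))
  raw <- raw_energy_within(all)
  raw["rep"] <- raw["rep"] + eng$prostrain
  raw
}

#' @keywords internal
engine_breakdown <- function(eng, rot, weights) {
  raw <- engine_full_raw(eng, rot)
  methods::new("EnergyBreakdown",
               total = weighted_total(raw, weights),
               rep = unname(raw["rep"]), att = unname(raw["att"]),
               solv = unname(raw["solv"]), hb = unname(raw["hb"]),
               weights = weights)
}

# Iterative best-rotamer sweeps; deterministic (ties resolved by lowest
# rotamer index, strict improvement required).  Returns rotamers, number of
# sweeps that changed something, convergence flag, and the E_total path.
#' @keywords internal
engine_pack <- function(eng, rot, weights, max_cycles = 10L) {
  k <- eng$k
  free <- which(vapply(eng$blocks, length, 0L) > 1L)
  e0 <- weighted_total(engine_full_raw(eng, rot), weights)
  path <- e0
  changed_cycles <- 0L
  converged <- length(free) == 0L
  if (!converged) {
    for (cycle in seq_len(max_cycles)) {
      changed <- FALSE
      for (p in free) {
        context <- cat_atomsets(c(list(eng$fixed),
                                  lapply(setdiff(seq_len(k), p), function(q)
                                    eng$blocks[[q]][[rot[q]]])))
        local <- vapply(eng$blocks[[p]], function(b) {
          weighted_total(raw_energy_between(b, context), weights) +
            weighted_total(raw_energy_within(b), weights)
        }, 0)
        best <- which.min(local)
        if (local[best] < local[rot[p]]) {
          path <- c(path, path[length(path)] - (local[rot[p]] - local[best]))
          rot[p] <- best
          changed <- TRUE
        }
      }
      if (!changed) { converged <- TRUE; break }
      changed_cycles <- changed_cycles + 1L
    }
  }
  list(rot = rot, changed_cycles = changed_cycles, converged = converged,
       path = path)
}

#' @keywords internal
engine_atoms_df <- function(eng, rot, assembly) {
  sets <- c(list(eng$fixed),
            lapply(seq_len(eng$k), function(p) eng$blocks[[p]][[rot[p]]]))
  all <- cat_atomsets(sets)
  info <- assembly@strandInfo
  df <- data.frame(strand = all$strand,
                   sheet = info$sheet[all$strand],
                   resno = all$resno,
                   resname = all$resname,
                   atom = all$name,
                   element = vapply(all$name, element_of, ""),
                   x = all$x, y = all$y, z = all$z,
                   stringsAsFactors = FALSE)
  df[order(df$strand, df$resno), , drop = FALSE]
}

#' @keywords internal
new_threaded_model <- function(eng, assembly, rot, weights, packed,
                               changed_cycles = 0L, converged = TRUE,
                               path = numeric(0)) {
  methods::new("ThreadedModel",
               templateName = assembly@template@name,
               sequence = paste(eng$seq, collapse = ""),
               assembly = assembly, rotamers = as.integer(rot),
               atoms = engine_atoms_df(eng, rot, assembly),
               energy = engine_breakdown(eng, rot, weights),
               packed = packed, changedCycles = as.integer(changed_cycles),
               converged = converged, energyPath = path)
}

# ---- exported operations ----------------------------------------------------

#' Graft a sequence onto every strand of a fibril assembly
#'
#' Places the query sequence on all strand copies (homotypic in-register
#' stacking) with every side chain at its first library rotamer, and scores
#' the resulting model.
#'
#' @param assembly a \code{\linkS4class{FibrilAssembly}}
#' @param sequence character string; length must equal the template length,
#'   standard one-letter codes only
#' @param weights energy weights (see \code{\link{defaultEnergyWeights}})
#' @param lib rotamer library (see \code{\link{rotamerLibrary}})
#' @return an unpacked \code{\linkS4class{ThreadedModel}}
#' @export
graftSequence <- function(assembly, sequence,
                          weights = defaultEnergyWeights(),
                          lib = rotamerLibrary()) {
  eng <- build_engine(assembly, sequence, lib)
  new_threaded_model(eng, assembly, rep(1L, eng$k), weights, packed = FALSE)
}

#' Optimize side-chain rotamers of a threaded model
#'
#' Iterative per-position best-rotamer sweeps, symmetry-coupled: all strand
#' copies adopt the same rotamer at each position.  Sweeps continue until no
#' single-position change lowers the total energy or \code{maxCycles} is
#' reached; the total energy is non-increasing across accepted changes.
#' Deterministic: equal-energy rotamers resolve to the lowest library index.
#'
#' @param model a \code{\linkS4class{ThreadedModel}}
#' @param lib rotamer library
#' @param maxCycles maximum number of sweeps (>= 1)
#' @param weights energy weights
#' @return a packed \code{\linkS4class{ThreadedModel}}
#' @export
packSideChains <- function(model, lib = rotamerLibrary(), maxCycles = 10L,
                           weights = model@energy@weights) {
  stopifnot(maxCycles >= 1L)
  eng <- build_engine(model@assembly, model@sequence, lib)
  res <- engine_pack(eng, model@rotamers, weights, maxCycles)
  new_threaded_model(eng, model@assembly, res$rot, weights, packed = TRUE,
                     changed_cycles = res$changed_cycles,
                     converged = res$converged, path = res$path)
}

#' Compute the decomposed energy of a threaded model
#'
#' Recomputes all four raw terms from the model's coordinates and applies
#' the given weights; the breakdown identity
#' \code{total = sum(weights * terms)} holds exactly.
#'
#' @param model a \code{\linkS4class{ThreadedModel}}
#' @param weights energy weights
#' @return an \code{\linkS4class{EnergyBreakdown}}
#' @export
computeEnergy <- function(model, weights = model@energy@weights) {
  if (any(!is.finite(as.matrix(model@atoms[, c("x", "y", "z")]))))
    stop("model contains non-finite coordinates")
  eng <- build_engine(model@assembly, model@sequence)
  engine_breakdown(eng, model@rotamers, weights)
}

#' Thread a sequence window onto a template
#'
#' Composition graft -> pack -> score in the template's standard fibril
#' context (two sheets of \code{nStrands} strands by default).
#' Deterministic for fixed inputs and library order.
#'
#' @param window sequence window (length = template length)
#' @param template a \code{\linkS4class{BackboneTemplate}}
#' @param weights energy weights
#' @param nStrands strands per sheet
#' @param nSheets number of sheets
#' @param maxCycles packing sweep limit
#' @param lib rotamer library
#' @return a packed \code{\linkS4class{ThreadedModel}}; its total energy is
#'   available via \code{\link{totalEnergy}}
#' @examples
#' \donttest{
#' tp <- builtinTemplates()
#' m <- threadWindow("SGMGGI", tp$ZIPPER_P1)
#' totalEnergy(m)
#' }
#' @export
threadWindow <- function(window, template,
                         weights = defaultEnergyWeights(),
                         nStrands = 5L, nSheets = 2L, maxCycles = 10L,
                         lib = rotamerLibrary()) {
  assembly <- expandFibril(template, nStrands, nSheets)
  eng <- build_engine(assembly, window, lib)
  res <- engine_pack(eng, rep(1L, eng$k), weights, maxCycles)
  new_threaded_model(eng, assembly, res$rot, weights, packed = TRUE,
                     changed_cycles = res$changed_cycles,
                     converged = res$converged, path = res$path)
}
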