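# Sequence and variant-table input.
#
# Protein sequences are carried as ProteinRecord objects: an accession, a
# one-letter sequence, and a numbering offset (the residue number of the
# first sequence character) that reconciles sequences printed without their
# initiator methionine with database residue numbering.
#
# The variant table is a package-defined TSV dialect: one row per single
# missense substitution in protein coordinates, with columns
# protein_id, position, wt, mut, significance, source.

#' @title ProteinRecord: a protein sequence with numbering offset
#' @slot id accession / identifier
#' @slot sequence one-letter amino-acid string (20 standard letters plus X)
#' @slot offset residue number of the first sequence character (>= 1)
#' @export
setClass("ProteinRecord",
  representation(id = "character", sequence = "character",
                 offset = "integer"))

setValidity("ProteinRecord", function(object) {
  msg <- character(0)
  if (!nzchar(object@sequence)) msg <- c(msg, "sequence must be non-empty")
  letters_ok <- strsplit(object@sequence, "")[[1L]] %in% c(AA1, "X")
  if (!all(letters_ok))
    msg <- c(msg, "sequence restricted to the 20 standard letters plus X")
  if (object@offset < 1L) msg <- c(msg, "numbering offset must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProteinRecord", function(object) {
  cat(sprintf("ProteinRecord %s: %d aa (numbering %d..%d)\n", object@id,
              nchar(object@sequence), object@offset,
              object@offset + nchar(object@sequence) - 1L))
})

#' Construct a ProteinRecord
#' @param id accession
#' @param sequence one-letter amino-acid string
#' @param offset residue number of the first character (default 1)
#' @return a \code{\linkS4class{ProteinRecord}}
#' @export
ProteinRecord <- function(id, sequence, offset = 1L) {
  methods::new("ProteinRecord", id = as.character(id),
               sequence = toupper(gsub("[[:space:]]", "", sequence)),
               offset = as.integer(offset))
}

#' Sequence length of a ProteinRecord
#' @param x a \code{ProteinRecord}
#' @export
proteinLength <- function(x) nchar(x@sequence)

#' Read protein sequences from a FASTA file
#'
#' One \code{\linkS4class{ProteinRecord}} per entry.  Sequences are
#' uppercased, whitespace is stripped, and any letter outside the 20
#' standard codes is mapped to \code{X} with a warning.  A header token
#' \code{offset=N} sets the record's numbering offset (default 1).
#'
#' @param path FASTA file
#' @return named list of \code{ProteinRecord} objects
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[[:space:]]+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  offsets <- rep(1L, length(set))
  has_off <- grepl("offset=([0-9]+)", headers)
  offsets[has_off] <- as.integer(sub(".*offset=([0-9]+).*", "\\1",
                                     headers[has_off]))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- toupper(gsub("[[:space:]]", "", as.character(set[[i]])))
    if (!nzchar(s)) stop("FASTA format error: empty sequence for ", ids[i])
    bad <- !strsplit(s, "")[[1L]] %in% c(AA1, "X")
    if (any(bad)) {
      warning(sum(bad), " unknown letter(s) in ", ids[i], " mapped to X")
      sv <- strsplit(s, "")[[1L]]
      sv[bad] <- "X"
      s <- paste(sv, collapse = "")
    }
    out[[i]] <- ProteinRecord(ids[i], s, offsets[i])
  }
  names(out) <- ids
  out
}

#' Write ProteinRecords to FASTA
#' @param proteins list of \code{ProteinRecord}
#' @param path output file
#' @return invisibly, the path
#' @export
writeProteinFasta <- function(proteins, path) {
  hdr <- vapply(proteins, function(p) {
    if (p@offset != 1L) paste0(p@id, " offset=", p@offset) else p@id
  }, "")
  seqs <- Biostrings::AAStringSet(vapply(proteins, function(p) p@sequence, ""))
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a missense variant table (TSV)
#'
#' Expects a header row with columns \code{protein_id}, \code{position},
#' \code{wt}, \code{mut}, \code{significance}, \code{source}.  Rows with
#' \code{wt == mut}, a non-integer position, or non-standard residue codes
#' are rejected with a warning; significance values outside
#' \{pathogenic, benign, other\} are coerced to \code{"other"} with a
#' warning.  Parsing is order-preserving.
#'
#' @param path TSV file
#' @return data.frame with columns \code{protein_id}, \code{position},
#'   \code{wt}, \code{mut}, \code{significance}, \code{source}
#' @export
readVariantTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("protein_id", "position", "wt", "mut", "significance", "source")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("variant table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[, need]
  pos <- suppressWarnings(as.integer(raw$position))
  bad_pos <- is.na(pos) | as.character(pos) != raw$position | pos < 1L
  raw$wt <- toupper(raw$wt); raw$mut <- toupper(raw$mut)
  bad_aa <- !(raw$wt %in% AA1) | !(raw$mut %in% AA1)
  degenerate <- raw$wt == raw$mut
  drop <- bad_pos | bad_aa | degenerate
  if (any(drop))
    warning(sum(drop), " variant row(s) rejected (", sum(degenerate),
            " with wt == mut, ", sum(bad_pos), " with invalid position, ",
            sum(bad_aa & !degenerate), " with non-standard residues)")
  out <- data.frame(protein_id = raw$protein_id, position = pos,
                    wt = raw$wt, mut = raw$mut,
                    significance = tolower(raw$significance),
                    source = raw$source, stringsAsFactors = FALSE)[!drop, ,
                                                                   drop = FALSE]
  odd <- !out$significance %in% c("pathogenic", "benign", "other")
  if (any(odd)) {
    warning(sum(odd), " significance value(s) outside ",
            "{pathogenic, benign, other} coerced to 'other'")
    out$significance[odd] <- "other"
  }
  rownames(out) <- NULL
  out
}

#' Write a variant table (TSV)
#' @param variants data.frame as returned by \code{\link{readVariantTable}}
#' @param path output file
#' @return invisibly, the path
#' @export
writeVariantTable <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
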