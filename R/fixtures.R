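# Bundled reference data: the KRT8 head-domain and alpha-synuclein
# sequences, the published table of pathogenic LARKS mutations with their
# wild-type/mutant hexapeptide windows, the crystallized KRT8 segment
# pairs, and a residue-frequency background for enrichment analysis.

# KRT8 head domain, residues 2-90 (printed without the initiator
# methionine, hence numbering offset 2)
KRT8_1_90_SEQ <- paste0(
  "SIRVTQKSYKVSTSGPRAFSSRSYTSGPGSRISSSSFSRVGSSNFRGGLGGGYGGASGM",
  "GGITAVTVNQSLLSPLVLEVDPNIQAVRTQ")

# human alpha-synuclein 1-140 (NACore region QVTNVGGAVVTGVTAV at 68-83)
ASYN_SEQ <- paste0(
  "MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVHGVATVAEKTK",
  "EQVTNVGGAVVTGVTAVAQKTVEGAGSIAAATGFVKKDQLGKNEEGAPQEGILEDMPVDP",
  "DNEAYEMPSEEGYQDYEPEA")

# Pathogenic mutations in LARKS predicted to increase steric-zipper
# propensity: protein, residue, wild-type and mutant residues, and the
# wild-type (LARKS) and mutant (zipper) hexapeptide windows.
LARKS_MUTATION_TABLE <- local({
  txt <- c(
    "FUS,191,G,S,SGGGYG,SSGGYG",
    "FUS,225,G,V,SGGGGG,SGGGVG",
    "FUS,230,G,C,GGGGGY,GGGCGY",
    "GATAD1,59,G,A,GFGAAT,AFGAAT",
    "hnRNPA1,304,S,N,GGSGSN,GGSGNN",
    "hnRNPA2,290,D,V,SGNYND,SGNYNV",
    "hnRNPA2,290,D,V,NYNDFG,NYNVFG",
    "KRT8,53,G,V,GLGGGY,GLGGVY",
    "KRT8,53,G,V,LGGGYG,LGGVYG",
    "KRT8,54,Y,C,GYGGAS,GCGGAS",
    "KRT8,54,Y,H,GYGGAS,GHGGAS",
    "KRT8,55,G,A,GYGGAS,GYAGAS",
    "KRT8,62,G,C,MGGITA,MGCITA",
    "KRT8,62,G,C,SGMGGI,SGMGCI",
    "KRT8,62,G,C,GGITAV,GCITAV",
    "PURA,40,G,R,GGGGSG,GRGGSG",
    "TDP43,290,G,A,GFGNSR,GFANSR",
    "TDP43,294,G,A,GNSRGG,GNSRAG",
    "TDP43,294,G,A,SRGGGA,SRAGGA",
    "TDP43,294,G,V,NSRGGG,NSRVGG",
    "TDP43,294,G,V,RGGGAG,RVGGAG",
    "TDP43,294,G,V,GNSRGG,GNSRVG",
    "TDP43,295,G,R,GGGAGL,GRGAGL",
    "TDP43,295,G,S,GGGAGL,GSGAGL",
    "TDP43,298,G,S,AGLGNN,ASLGNN")
  out <- utils::read.csv(text = paste(txt, collapse = "\n"), header = FALSE,
                         stringsAsFactors = FALSE)
  names(out) <- c("protein", "position", "wt", "mut", "wt_window",
                  "mut_window")
  out
})

# Approximate residue frequencies in beta-sheet regions of globular
# proteins (package-supplied background for enrichment ratios; normalized)
BETA_SHEET_FREQUENCIES <- local({
  f <- c(A = 0.070, R = 0.045, N = 0.035, D = 0.040, C = 0.020,
         Q = 0.030, E = 0.045, G = 0.060, H = 0.025, I = 0.075,
         L = 0.090, K = 0.050, M = 0.025, F = 0.050, P = 0.020,
         S = 0.060, T = 0.070, W = 0.015, Y = 0.045, V = 0.090)
  f / sum(f)
})

#' Bundled reference fixtures
#'
#' Returns the bundled study material used throughout tests and examples:
#' the KRT8 head-domain (residues 2-90, numbering offset 2) and
#' alpha-synuclein sequences; the crystallized KRT8 segment pairs
#' (SGMGGIT/SGMGCIT at 58-64 and GGYGGAS/GGYAGAS at 52-58, plus the
#' mutant-only Y54H entry); the experimentally characterized KRT8 and FUS
#' variants; the full table of pathogenic LARKS mutations with their
#' wild-type/mutant hexapeptide windows; and a beta-sheet residue-frequency
#' background.
#'
#' The \code{accessions} element records the wwPDB entries deposited for
#' the crystallized segments (7K3C, 7K3X, 7K3Y); see
#' \code{\link{standinStructure}} for synthetic idealized reconstructions
#' usable offline.
#'
#' @return a named list; see Details
#' @examples
#' fx <- referenceFixtures()
#' fx$proteins$KRT8@offset
#' @export
referenceFixtures <- function() {
  proteins <- list(KRT8 = ProteinRecord("KRT8", KRT8_1_90_SEQ, offset = 2L),
                   ASYN = ProteinRecord("ASYN", ASYN_SEQ, offset = 1L))
  segment_pairs <- data.frame(
    variant = c("G62C", "G55A", "Y54H"),
    start = c(58L, 52L, 52L), end = c(64L, 58L, 58L),
    wt_segment = c("SGMGGIT", "GGYGGAS", "GGYGGAS"),
    mut_segment = c("SGMGCIT", "GGYAGAS", "GGHGGAS"),
    wt_crystallized = c(TRUE, FALSE, FALSE),
    mut_crystallized = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  variants <- data.frame(
    protein_id = c(rep("KRT8", 3L), rep("FUS", 3L)),
    position = c(54L, 55L, 62L, 191L, 225L, 230L),
    wt = c("Y", "G", "G", "G", "G", "G"),
    mut = c("H", "A", "C", "S", "V", "C"),
    significance = "pathogenic",
    source = "curated",
    stringsAsFactors = FALSE)
  list(proteins = proteins,
       variants = variants,
       segment_pairs = segment_pairs,
       mutation_table = LARKS_MUTATION_TABLE,
       beta_frequencies = BETA_SHEET_FREQUENCIES,
       accessions = data.frame(
         accession = c("7K3C", "7K3X", "7K3Y"),
         segment = c("SGMGGIT", "SGMGCIT", "GGYAGAS"),
         stringsAsFactors = FALSE))
}

#' Calibration control sequences
#'
#' The two control sets behind the shipped thresholds: positives are the
#' glycine-rich wild-type hexapeptide windows of the bundled mutation
#' table (plus the three template namesakes); negatives are scrambled
#' charged/bulky hexapeptides incompatible with kinked backbones.
#'
#' @return list with elements \code{positives} and \code{negatives}
#'   (character vectors of hexapeptides)
#' @export
calibrationControls <- function() {
  list(
    positives = unique(c(LARKS_MUTATION_TABLE$wt_window,
                         "STGGYS", "SYSGYS", "GYNGFG")),
    negatives = c("WKEWRF", "EKRDWF", "KRREKD", "FWFYWL", "KDEREK",
                  "WLFKYR", "DKEWIE", "RFWEKD", "ILVWFM", "EEKKRR",
                  "YWFLIV", "DREEKW", "YLWFIV", "VWIFLY")
  )
}
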