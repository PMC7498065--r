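# Codon-level utilities: three-frame translation and a fixed
# reverse-translation table used by the synthetic repertoire generator.

# One representative codon per amino acid (mammalian-frequent choices where
# it matters little; Cys is TGT so that a single third-position change
# switches TGT <-> TGC silently).
.CODON_OF <- c(
  A = "GCA", R = "AGA", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "AGT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT"
)

#' Reverse-translate an amino-acid string with a fixed codon table
#'
#' Deterministic helper used to build synthetic germline segments: each
#' residue maps to one fixed codon, so nucleotide-level ground truth is
#' reproducible.
#'
#' @param aa Character scalar over the 20 standard residues.
#' @return Character scalar of nucleotides, length `3 * nchar(aa)`.
#' @examples
#' reverseTranslate("CDK")
#' @export
reverseTranslate <- function(aa) {
  res <- strsplit(aa, "")[[1]]
  bad <- setdiff(res, names(.CODON_OF))
  if (length(bad))
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
  paste(.CODON_OF[res], collapse = "")
}

# Fast frame-0 translation via the standard genetic code lookup table;
# codons containing anything but A/C/G/T render "X". Used on the
# generator's hot path; the public three-frame API delegates to
# Biostrings.
#' @noRd
.translateFast <- function(nt) {
  n <- (nchar(nt) %/% 3L) * 3L
  if (n < 3L) return("")
  codons <- substring(nt, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate a nucleotide sequence in all three forward frames
#'
#' Frame `f` (0, 1, 2) starts at 0-based offset `f`; the trailing partial
#' codon is dropped; the standard codon table is used; stop codons are
#' rendered `"*"`; codons containing `N` are rendered `"X"`.
#'
#' @param nt Character scalar or [Biostrings::DNAString] over `{A,C,G,T,N}`.
#' @return Named character vector of length 3 (`frame0`, `frame1`,
#'   `frame2`). Frames shorter than one codon translate to `""`.
#' @examples
#' translateThreeFrames("ATGGCC")
#' @export
translateThreeFrames <- function(nt) {
  nt <- as.character(nt)
  if (length(nt) != 1L || is.na(nt))
    stop("nt must be a single sequence")
  n <- nchar(nt)
  out <- character(3)
  for (f in 0:2) {
    w <- ((n - f) %/% 3L) * 3L
    if (w < 3L) {
      out[f + 1L] <- ""
      next
    }
    sub <- Biostrings::subseq(Biostrings::DNAString(nt), start = f + 1L,
                              width = w)
    out[f + 1L] <- as.character(
      Biostrings::translate(sub, if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  names(out) <- paste0("frame", 0:2)
  out
}
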