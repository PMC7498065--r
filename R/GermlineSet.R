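# GermlineSet: the V/D/J segment pools the synthetic repertoire draws from.

#' GermlineSet: germline segments for repertoire simulation
#'
#' Holds CDRH3-proximal germline nucleotide segments: V tails (each
#' beginning at the conserved junction cysteine codon), D segments (one of
#' which is flagged as the ultralong knob core, playing the role of bovine
#' IGHD8-2), J segments, and the short V-gene tail whose tandem duplication
#' marks ultralong rearrangements (the IGHV1-7 hallmark).
#'
#' The segments bundled with the package (see [defaultGermlineSet()]) are a
#' synthetic stand-in designed to reproduce the statistical architecture of
#' bovine CDRH3 (a 4-cysteine knob core rich in Gly/Tyr/Ser, a duplicated
#' ascending-stalk unit, and an aromatic-aliphatic descending stalk), not
#' real bovine germline sequences; real germlines can be substituted via
#' [readGermlineSet()].
#'
#' @slot vSegments,dSegments,jSegments [Biostrings::DNAStringSet] pools.
#' @slot ighd82Name Name of the D segment carrying the ultralong knob core.
#' @slot ighv17Tail [Biostrings::DNAString]-coercible character: the
#'   duplication unit.
#'
#' @name GermlineSet-class
#' @aliases GermlineSet
#' @exportClass GermlineSet
setClass("GermlineSet",
  representation(
    vSegments = "DNAStringSet",
    dSegments = "DNAStringSet",
    jSegments = "DNAStringSet",
    ighd82Name = "character",
    ighv17Tail = "character"
  )
)

setValidity("GermlineSet", function(object) {
  msg <- character()
  for (nm in c("vSegments", "dSegments", "jSegments")) {
    s <- slot(object, nm)
    if (length(s) == 0L) msg <- c(msg, paste0(nm, " is empty"))
    else if (is.null(names(s)) || anyDuplicated(names(s)))
      msg <- c(msg, paste0(nm, " must have unique names"))
    if (length(s) && !all(grepl("^[ACGT]+$", as.character(s))))
      msg <- c(msg, paste0(nm, " must be over {A,C,G,T}"))
  }
  if (length(object@ighd82Name) != 1L ||
      !(object@ighd82Name %in% names(object@dSegments))) {
    msg <- c(msg, "ighd82Name must name one D segment")
  } else {
    core <- as.character(object@dSegments[[object@ighd82Name]])
    if (nchar(core) %% 3L != 0L) {
      msg <- c(msg, "ultralong core length must be a multiple of 3")
    } else {
      aa <- translateThreeFrames(core)[["frame0"]]
      nC <- sum(strsplit(aa, "")[[1]] == "C")
      if (nC != 4L)
        msg <- c(msg, sprintf(
          "ultralong core must encode exactly 4 cysteines (found %d)", nC))
    }
  }
  if (length(object@ighv17Tail) != 1L ||
      !grepl("^[ACGT]+$", object@ighv17Tail))
    msg <- c(msg, "ighv17Tail must be a single {A,C,G,T} sequence")
  if (length(msg)) msg else TRUE
})

#' @describeIn GermlineSet-class Construct a GermlineSet.
#' @param vSegments,dSegments,jSegments Named character vectors or
#'   `DNAStringSet`s of germline nucleotide segments.
#' @param ighd82Name Name of the D segment with the ultralong-core role.
#' @param ighv17Tail Duplication-unit nucleotide sequence.
#' @export
GermlineSet <- function(vSegments, dSegments, jSegments, ighd82Name,
                        ighv17Tail) {
  new("GermlineSet",
      vSegments = Biostrings::DNAStringSet(vSegments),
      dSegments = Biostrings::DNAStringSet(dSegments),
      jSegments = Biostrings::DNAStringSet(jSegments),
      ighd82Name = ighd82Name,
      ighv17Tail = as.character(ighv17Tail))
}

#' @describeIn GermlineSet-class V-segment accessor.
#' @param x A `GermlineSet`.
#' @export
vSegments <- function(x) x@vSegments

#' @describeIn GermlineSet-class D-segment accessor.
#' @export
dSegments <- function(x) x@dSegments

#' @describeIn GermlineSet-class J-segment accessor.
#' @export
jSegments <- function(x) x@jSegments

#' @describeIn GermlineSet-class Nucleotide sequence of the ultralong knob
#'   core (the IGHD8-2-role D segment).
#' @export
ultralongCore <- function(x) as.character(x@dSegments[[x@ighd82Name]])

#' @describeIn GermlineSet-class Amino-acid translation of the knob core.
#' @export
ultralongCoreAa <- function(x)
  translateThreeFrames(ultralongCore(x))[["frame0"]]

#' @describeIn GermlineSet-class The duplication-unit sequence.
#' @export
duplicationTail <- function(x) x@ighv17Tail

setMethod("show", "GermlineSet", function(object) {
  cat("GermlineSet with", length(object@vSegments), "V,",
      length(object@dSegments), "D,", length(object@jSegments),
      "J segments\n")
  cat("  ultralong core (", object@ighd82Name, "): ",
      ultralongCoreAa(object), "\n", sep = "")
  cat("  duplication tail: ", object@ighv17Tail, "\n", sep = "")
})

# Synthetic stand-in germline segments. Amino-acid designs:
#   V tails    : CAK, CAR, CVR      (begin at the conserved junction Cys)
#   regular D  : DYGGNSY, GITTVV, SGYDYDY
#   knob core  : GYSCPDGYSYGYCSYGYDSCYGYEYSSYC  (exactly 4 Cys, Gly/Tyr/Ser
#                rich so single-nucleotide changes can create cysteines)
#   J segments : YFDY, ALDY and the stalk-bearing VAYVYIW whose
#                aromatic-aliphatic alternation forms a descending stalk
#   dup tail   : TTVHQ (ascending-stalk unit, present twice in ultralong
#                rearrangements)

#' Bundled synthetic germline segment set
#'
#' Returns the synthetic stand-in [GermlineSet] used throughout the test
#' suite and documentation. A FASTA rendering with role annotations ships
#' under `inst/extdata/synthetic_germlines.fasta`.
#'
#' @return A [GermlineSet].
#' @examples
#' defaultGermlineSet()
#' @export
defaultGermlineSet <- function() {
  v <- vapply(c(IGHV1 = "CAK", IGHV2 = "CAR", IGHV3 = "CVR"),
              reverseTranslate, character(1))
  d <- vapply(c(IGHD1 = "DYGGNSY", IGHD2 = "GITTVV", IGHD3 = "SGYDYDY",
                `IGHD8-2` = "GYSCPDGYSYGYCSYGYDSCYGYEYSSYC"),
              reverseTranslate, character(1))
  j <- vapply(c(IGHJ1 = "YFDY", IGHJ2 = "ALDY", IGHJ3 = "VAYVYIW"),
              reverseTranslate, character(1))
  GermlineSet(v, d, j, ighd82Name = "IGHD8-2",
              ighv17Tail = reverseTranslate("TTVHQ"))
}

#' Read / write a GermlineSet as annotated FASTA
#'
#' Each record's description line carries `role=V|D|J|duplication_tail`,
#' with the ultralong-core D additionally tagged `ultralong_core`.
#'
#' @param path FASTA file path.
#' @return `readGermlineSet` returns a [GermlineSet]; `writeGermlineSet`
#'   invisibly returns `path`.
#' @export
readGermlineSet <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  hdr <- names(s)
  id <- sub("\\s.*$", "", hdr)
  role <- sub(".*role=(\\S+).*", "\\1", hdr)
  core <- grepl("ultralong_core", hdr)
  pick <- function(r) {
    out <- as.character(s[role == r])
    names(out) <- id[role == r]
    out
  }
  tailSeq <- pick("duplication_tail")
  if (length(tailSeq) != 1L)
    stop("expected exactly one record with role=duplication_tail")
  if (sum(core) != 1L)
    stop("expected exactly one D record tagged ultralong_core")
  GermlineSet(pick("V"), pick("D"), pick("J"),
              ighd82Name = id[core], ighv17Tail = unname(tailSeq))
}

#' @rdname readGermlineSet
#' @param x A [GermlineSet].
#' @export
writeGermlineSet <- function(x, path) {
  rec <- function(seqs, role, coreName = NULL) {
    out <- as.character(seqs)
    tag <- paste0(names(out), " role=", role)
    if (!is.null(coreName))
      tag[names(out) == coreName] <- paste(tag[names(out) == coreName],
                                           "ultralong_core")
    names(out) <- tag
    out
  }
  all <- c(rec(x@vSegments, "V"),
           rec(x@dSegments, "D", x@ighd82Name),
           rec(x@jSegments, "J"),
           setNames(x@ighv17Tail, "IGHV1-7-tail role=duplication_tail"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(all), path)
  invisible(path)
}
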