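# Knob/stalk partitioning of ultralong CDRH3 and cleavable fusion design.

.AROMATIC <- c("F", "W", "Y")
.ALIPHATIC <- c("A", "V", "L", "I")
.TEV_LEADER <- "MEWSWVFLFFLSVTTGVHS"   # murine heavy-chain leader
.TEV_MOTIF_RX <- "ENLYFQ(?=[GS])"      # cleavage after Q of ENLYFQ|(G/S)

# 0-based start of the first aromatic-initial aromatic/aliphatic
# alternation of length >= minAlt strictly after `afterIdx`, or NA.
#' @noRd
.firstAlternationStart <- function(aa, afterIdx, aromatic = .AROMATIC,
                                   aliphatic = .ALIPHATIC, minAlt = 3L) {
  res <- strsplit(aa, "")[[1]]
  n <- length(res)
  cls <- ifelse(res %in% aromatic, "aro",
                ifelse(res %in% aliphatic, "ali", NA_character_))
  from <- afterIdx + 2L    # first candidate, 1-based
  if (from < 1L) from <- 1L
  for (s in seq.int(from, length.out = max(0L, n - from + 1L))) {
    if (is.na(cls[s]) || cls[s] != "aro") next
    run <- 1L
    while (s + run <= n && !is.na(cls[s + run]) &&
           cls[s + run] != cls[s + run - 1L]) run <- run + 1L
    if (run >= minAlt) return(s - 1L)
  }
  NA_integer_
}

# C-terminal knob boundary (0-based, half-open end) given the 0-based
# index of the last germline cysteine: the position after the last
# aliphatic residue preceding the descending-stalk alternation; the
# sequence end when no alternation exists.
#' @noRd
.knobEndFromScan <- function(aa, lastCysIdx, aromatic = .AROMATIC,
                             aliphatic = .ALIPHATIC, minAlt = 3L) {
  s <- .firstAlternationStart(aa, lastCysIdx, aromatic, aliphatic, minAlt)
  if (is.na(s)) return(nchar(aa))
  res <- strsplit(aa, "")[[1]]
  ali <- which(res %in% aliphatic) - 1L
  ali <- ali[ali < s]
  if (!length(ali)) s else max(ali) + 1L
}

#' KnobAnnotation: knob/stalk partition of an ultralong CDRH3
#'
#' The three pieces concatenate exactly to the CDRH3:
#' `ascendingStalk | knob | descendingStalk`.
#'
#' @slot cdrh3Aa The full CDRH3 amino-acid sequence.
#' @slot knobSpan 0-based half-open residue interval of the knob.
#' @slot ascendingStalk,descendingStalk Prefix/suffix around the knob.
#' @slot germlineCysIndices 0-based CDRH3 positions aligned to the
#'   germline core cysteines.
#' @name KnobAnnotation-class
#' @aliases KnobAnnotation
#' @exportClass KnobAnnotation
setClass("KnobAnnotation",
  representation(
    cdrh3Aa = "character",
    knobSpan = "integer",
    ascendingStalk = "character",
    descendingStalk = "character",
    germlineCysIndices = "integer"
  )
)

setValidity("KnobAnnotation", function(object) {
  msg <- character()
  sp <- object@knobSpan
  if (length(sp) != 2L || sp[1L] >= sp[2L])
    msg <- c(msg, "knobSpan must be a non-empty half-open interval")
  recon <- paste0(object@ascendingStalk, knobSequence(object),
                  object@descendingStalk)
  if (!identical(recon, object@cdrh3Aa))
    msg <- c(msg, "stalk/knob/stalk must concatenate to the CDRH3")
  if (length(msg)) msg else TRUE
})

#' @describeIn KnobAnnotation-class The knob amino-acid sequence.
#' @param x A `KnobAnnotation`.
#' @export
knobSequence <- function(x)
  substr(x@cdrh3Aa, x@knobSpan[1L] + 1L, x@knobSpan[2L])

#' @describeIn KnobAnnotation-class The knob span (0-based half-open).
#' @export
knobSpan <- function(x) x@knobSpan

setMethod("show", "KnobAnnotation", function(object) {
  cat(sprintf("KnobAnnotation: knob [%d, %d) of %d aa\n",
              object@knobSpan[1L], object@knobSpan[2L],
              nchar(object@cdrh3Aa)))
  cat("  ", object@ascendingStalk, " | ", knobSequence(object), " | ",
      object@descendingStalk, "\n", sep = "")
})

#' Map germline-core cysteines onto a CDRH3
#'
#' Locally aligns the knob-core germline peptide (IGHD8-2 role) against
#' the CDRH3 (same scoring as [pairwiseIdentity()]) and reports the CDRH3
#' positions aligned to the core's cysteines - including positions where
#' hypermutation has replaced the cysteine, which are flagged `mutated`.
#' An alignment scoring below half of the core's self-score raises an
#' error (`core not found`).
#'
#' @param cdrh3Aa CDRH3 amino-acid sequence.
#' @param coreAa Germline core peptide (>= 1 cysteine); defaults to the
#'   bundled synthetic core.
#' @return `data.frame(core_pos, cdrh3_pos, residue, mutated)` with
#'   0-based positions; core cysteines deleted in the CDRH3 are omitted
#'   (with a warning).
#' @export
mapGermlineCysteines <- function(cdrh3Aa,
                                 coreAa = ultralongCoreAa(defaultGermlineSet())) {
  coreRes <- strsplit(coreAa, "")[[1]]
  coreCys <- which(coreRes == "C")
  if (!length(coreCys)) stop("core peptide must contain >= 1 cysteine")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(coreAa), Biostrings::AAString(cdrh3Aa),
    substitutionMatrix = .identityMatrix(),
    gapOpening = 10, gapExtension = 1, type = "local")
  selfScore <- nchar(coreAa)    # match = +1
  if (Biostrings::score(aln) < 0.5 * selfScore)
    stop("core not found: best local alignment scores ",
         format(Biostrings::score(aln)), " < ", 0.5 * selfScore)
  pAln <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sAln <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pPos <- Biostrings::pattern(aln)@range@start      # 1-based core start
  sPos <- Biostrings::subject(aln)@range@start      # 1-based cdrh3 start
  corePos <- cdrPos <- integer(length(pAln))
  pi <- pPos - 1L; si <- sPos - 1L
  for (k in seq_along(pAln)) {
    if (pAln[k] != "-") pi <- pi + 1L
    if (sAln[k] != "-") si <- si + 1L
    corePos[k] <- if (pAln[k] != "-") pi else NA_integer_
    cdrPos[k] <- if (sAln[k] != "-") si else NA_integer_
  }
  rows <- lapply(coreCys, function(cc) {
    k <- which(corePos == cc)
    if (!length(k) || is.na(cdrPos[k])) return(NULL)
    data.frame(core_pos = cc - 1L, cdrh3_pos = cdrPos[k] - 1L,
               residue = sAln[k], mutated = sAln[k] != "C",
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L)
    warning(dropped, " core cysteine(s) aligned to a gap and were omitted")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L)
    stop("core not found: no core cysteine could be mapped")
  rownames(out) <- NULL
  out
}

#' Call knob/stalk boundaries on an ultralong CDRH3
#'
#' The knob N-terminus is the single residue immediately preceding the
#' first germline cysteine (the first residue of the D segment). The knob
#' C-terminus is the final aliphatic residue preceding the
#' aromatic-aliphatic alternation of the descending stalk: scanning the
#' suffix after the last germline cysteine, the first aromatic-initial
#' run of at least `minAlternation` residues alternating between the
#' aromatic and aliphatic classes marks the stalk; the knob ends after
#' the last aliphatic residue before that run. When no such run exists
#' the knob extends to the sequence end (empty descending stalk, with a
#' warning).
#'
#' @param cdrh3Aa CDRH3 amino-acid sequence.
#' @param germlineCysIndices 0-based positions of the germline cysteines
#'   (as from [mapGermlineCysteines()]); the first must be >= 1.
#' @param aromaticSet,aliphaticSet Residue classes (His and Met belong to
#'   neither by default).
#' @param minAlternation Minimum alternation length calling the stalk.
#' @return A [KnobAnnotation].
#' @examples
#' callKnobBoundaries("TTVHQKTCPDGSCVAYVYIW", c(7L, 12L))
#' @export
callKnobBoundaries <- function(cdrh3Aa, germlineCysIndices,
                               aromaticSet = .AROMATIC,
                               aliphaticSet = .ALIPHATIC,
                               minAlternation = 3L) {
  if (!length(germlineCysIndices)) stop("germlineCysIndices is empty")
  germlineCysIndices <- sort(as.integer(germlineCysIndices))
  firstCys <- germlineCysIndices[1L]
  lastCys <- germlineCysIndices[length(germlineCysIndices)]
  if (firstCys < 1L)
    stop("first germline cysteine at index 0: no preceding residue ",
         "to start the knob")
  start <- firstCys - 1L
  end <- .knobEndFromScan(cdrh3Aa, lastCys, aromaticSet, aliphaticSet,
                          minAlternation)
  if (end == nchar(cdrh3Aa) &&
      is.na(.firstAlternationStart(cdrh3Aa, lastCys, aromaticSet,
                                   aliphaticSet, minAlternation)))
    warning("no descending-stalk alternation found; knob extends to the ",
            "sequence end")
  new("KnobAnnotation",
      cdrh3Aa = cdrh3Aa,
      knobSpan = c(start, end),
      ascendingStalk = substr(cdrh3Aa, 1L, start),
      descendingStalk = substr(cdrh3Aa, end + 1L, nchar(cdrh3Aa)),
      germlineCysIndices = germlineCysIndices)
}

#' FusionConstruct: a designed ORF carrying a CDRH3 or knob insert
#'
#' @slot constructType `"cdrh3_scfc"` or `"fab_knob"`.
#' @slot orfAa Full amino-acid ORF.
#' @slot leaderAa Secretion leader (empty for Fab-knob grafts).
#' @slot tevSites 0-based positions of each `ENLYFQ(G/S)` recognition
#'   motif in the ORF.
#' @slot insertSpan 0-based half-open interval of the insert in the ORF.
#' @name FusionConstruct-class
#' @aliases FusionConstruct
#' @exportClass FusionConstruct
setClass("FusionConstruct",
  representation(
    constructType = "character",
    orfAa = "character",
    leaderAa = "character",
    tevSites = "integer",
    insertSpan = "integer"
  )
)

setValidity("FusionConstruct", function(object) {
  msg <- character()
  if (!(object@constructType %in% c("cdrh3_scfc", "fab_knob")))
    msg <- c(msg, "unknown constructType")
  if (nzchar(object@leaderAa) && !startsWith(object@orfAa, object@leaderAa))
    msg <- c(msg, "orf must begin with the leader")
  for (p in object@tevSites) {
    if (substr(object@orfAa, p + 1L, p + 6L) != "ENLYFQ" ||
        !(substr(object@orfAa, p + 7L, p + 7L) %in% c("G", "S")))
      msg <- c(msg, "tevSites must point at ENLYFQ(G/S) motifs")
  }
  sp <- object@insertSpan
  if (length(sp) != 2L || sp[1L] < 0L || sp[2L] > nchar(object@orfAa) ||
      sp[1L] >= sp[2L])
    msg <- c(msg, "insertSpan must be a non-empty interval within the ORF")
  if (length(msg)) msg else TRUE
})

#' @describeIn FusionConstruct-class The full ORF sequence.
#' @param x A `FusionConstruct`.
#' @export
orfSequence <- function(x) x@orfAa

#' @describeIn FusionConstruct-class 0-based TEV motif positions.
#' @export
tevSites <- function(x) x@tevSites

#' @describeIn FusionConstruct-class The insert interval (0-based
#'   half-open).
#' @export
insertSpan <- function(x) x@insertSpan

setMethod("show", "FusionConstruct", function(object) {
  cat(sprintf("FusionConstruct (%s): %d aa, insert [%d, %d), %d TEV site(s)\n",
              object@constructType, nchar(object@orfAa),
              object@insertSpan[1L], object@insertSpan[2L],
              length(object@tevSites)))
})

#' @noRd
.findTevSites <- function(orf) {
  m <- gregexpr(.TEV_MOTIF_RX, orf, perl = TRUE)[[1]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Design a CDRH3-ScFc fusion construct
#'
#' ORF layout: `leader + CDRH3 + ScFc template`, where the template is a
#' TEV-cleavable, poly-His-tagged single-chain Fc (both Fc halves as one
#' polypeptide, giving a monovalent fusion partner). The template must
#' contain a TEV recognition motif and a poly-His tract.
#'
#' @param cdrh3Aa Non-empty CDRH3 amino-acid sequence.
#' @param scfcTemplateAa ScFc template (defaults to the bundled synthetic
#'   stand-in).
#' @param leaderAa Secretion leader.
#' @return A [FusionConstruct] of type `"cdrh3_scfc"`.
#' @export
buildCdrh3ScFc <- function(cdrh3Aa, scfcTemplateAa = defaultScFcTemplate(),
                           leaderAa = .TEV_LEADER) {
  if (!nzchar(cdrh3Aa)) stop("cdrh3Aa must be non-empty")
  if (!grepl(.TEV_MOTIF_RX, scfcTemplateAa, perl = TRUE))
    stop("ScFc template lacks a TEV recognition motif")
  if (!grepl("H{6,}", scfcTemplateAa))
    stop("ScFc template lacks a poly-His tract")
  orf <- paste0(leaderAa, cdrh3Aa, scfcTemplateAa)
  new("FusionConstruct",
      constructType = "cdrh3_scfc", orfAa = orf, leaderAa = leaderAa,
      tevSites = .findTevSites(orf),
      insertSpan = c(nchar(leaderAa), nchar(leaderAa) + nchar(cdrh3Aa)))
}

#' Graft a knob into an acceptor Fab CDRH3, flanked by TEV sites
#'
#' ORF layout: `acceptor[0:i] + TEV + knob + TEV + acceptor[i:]` with `i`
#' the 0-based insertion point inside the acceptor's CDRH3, so TEV
#' digestion releases the knob from the Fab scaffold.
#'
#' @param knobAa Non-empty knob amino-acid sequence.
#' @param acceptorHeavyAa Acceptor heavy-chain sequence.
#' @param insertionPoint 0-based insertion index within the acceptor.
#' @param tevSiteAa TEV recognition + P1' residue (default `ENLYFQG`).
#' @return A [FusionConstruct] of type `"fab_knob"`.
#' @examples
#' buildFabKnobFusion("KCK", "AAAA", 2L)
#' @export
buildFabKnobFusion <- function(knobAa, acceptorHeavyAa, insertionPoint,
                               tevSiteAa = "ENLYFQG") {
  if (!nzchar(knobAa)) stop("knobAa must be non-empty")
  if (insertionPoint < 0L || insertionPoint > nchar(acceptorHeavyAa))
    stop("insertionPoint outside the acceptor sequence")
  if (!grepl(.TEV_MOTIF_RX, tevSiteAa, perl = TRUE))
    stop("tevSiteAa is not a TEV recognition motif")
  pre <- substr(acceptorHeavyAa, 1L, insertionPoint)
  post <- substr(acceptorHeavyAa, insertionPoint + 1L,
                 nchar(acceptorHeavyAa))
  orf <- paste0(pre, tevSiteAa, knobAa, tevSiteAa, post)
  insStart <- nchar(pre) + nchar(tevSiteAa)
  new("FusionConstruct",
      constructType = "fab_knob", orfAa = orf, leaderAa = "",
      tevSites = .findTevSites(orf),
      insertSpan = c(insStart, insStart + nchar(knobAa)))
}

#' Digest an ORF with TEV protease in silico
#'
#' Cleaves after the Q of every `ENLYFQ` followed by `G` or `S`. The
#' fragments always concatenate back to the input; for a doubly flanked
#' knob graft the middle fragment is `G/S remnant + knob + ENLYFQ`
#' (remnant bookkeeping is explicit in the `n_term_remnant` /
#' `c_term_motif` columns).
#'
#' @param orfAa Amino-acid sequence.
#' @return `data.frame(fragment, start, end, n_term_remnant,
#'   c_term_motif)` with 0-based half-open coordinates; a single row equal
#'   to the input when there is no site.
#' @examples
#' tevDigest("AAENLYFQGBB")
#' @export
tevDigest <- function(orfAa) {
  sites <- .findTevSites(orfAa)
  cuts <- c(0L, sites + 6L, nchar(orfAa))   # cut after Q (motif pos + 6)
  cuts <- unique(cuts)
  starts <- head(cuts, -1L)
  ends <- cuts[-1L]
  frag <- substring(orfAa, starts + 1L, ends)
  data.frame(
    fragment = frag,
    start = starts, end = ends,
    n_term_remnant = c(NA_character_, substr(frag[-1L], 1L, 1L)),
    c_term_motif = c(endsWith(frag, "ENLYFQ")),
    stringsAsFactors = FALSE)
}
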