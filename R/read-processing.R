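# Read processing: demultiplexing, motif-anchored CDRH3 extraction from
# three-frame translations, deduplication.

.UPSTREAM_MOTIF <- "DSATYY"
.DOWNSTREAM_MOTIFS <- c("LLVTVSS", "LLITVSS")

# "none" result carrying a machine-readable reason code
#' @noRd
.none <- function(reason)
  structure(list(), reason = reason, class = "knobminer_none")

#' Test for the "none" result of extraction/collection
#'
#' [extractCdrh3()] and [collectCdrh3()] return a zero-length sentinel
#' (with a `reason` attribute) when a read yields no usable CDRH3.
#'
#' @param x Any object.
#' @return `TRUE` for the sentinel, otherwise `FALSE`.
#' @export
isNone <- function(x) inherits(x, "knobminer_none")

#' @rdname isNone
#' @export
noneReason <- function(x) if (isNone(x)) attr(x, "reason") else NA_character_

#' Demultiplex reads by 8-nt barcode
#'
#' The barcode occupies the eight bases immediately after the fixed
#' sequencing adaptor. Reads whose barcode matches no sheet entry within
#' `maxMismatch` go to the `undetermined` bin. The barcode sheet must be
#' unambiguous: all mutual Hamming distances must exceed `2 * maxMismatch`.
#'
#' @param reads A [Biostrings::DNAStringSet] (or coercible) of raw reads.
#' @param barcodes Distinct 8-nt barcodes.
#' @param maxMismatch Maximum Hamming distance for a barcode call.
#' @param adaptorLength Offset of the barcode (defaults to the bundled
#'   A-adaptor length).
#' @return Named list of `DNAStringSet` bins (one per barcode, plus
#'   `undetermined`); bin sizes always sum to the input size.
#' @export
demultiplexReads <- function(reads, barcodes, maxMismatch = 1L,
                             adaptorLength = nchar(.ADAPTOR_A)) {
  reads <- Biostrings::DNAStringSet(reads)
  .assertDna(barcodes, "barcodes")
  if (any(nchar(barcodes) != 8L)) stop("barcodes must be 8 nt long")
  if (anyDuplicated(barcodes)) stop("barcodes must be distinct")
  if (length(barcodes) > 1L) {
    pairs <- utils::combn(barcodes, 2L)
    dmin <- min(apply(pairs, 2L, function(p) .hamming(p[1L], p[2L])))
    if (dmin <= 2L * maxMismatch)
      stop("ambiguous barcode set: minimum mutual Hamming distance ", dmin,
           " does not exceed 2 * maxMismatch = ", 2L * maxMismatch)
  }
  obs <- substr(as.character(reads), adaptorLength + 1L, adaptorLength + 8L)
  dists <- vapply(barcodes, function(b)
    vapply(obs, function(o)
      if (nchar(o) == 8L) .hamming(o, b) else 8L, numeric(1), USE.NAMES = FALSE),
    numeric(length(obs)))
  dists <- matrix(dists, ncol = length(barcodes))
  best <- max.col(-dists, ties.method = "first")
  bestD <- dists[cbind(seq_along(obs), best)]
  call <- ifelse(bestD <= maxMismatch, barcodes[best], "undetermined")
  bins <- lapply(c(barcodes, "undetermined"), function(b) reads[call == b])
  names(bins) <- c(barcodes, "undetermined")
  bins
}

#' Extract the CDRH3 from an amino-acid translation
#'
#' Returns the residues strictly between the end of the upstream
#' framework-3 motif (`DSATYY`) and the start of the downstream
#' framework-4 motif (`LLVTVSS` or `LLITVSS`), i.e. the region reported as
#' Kabat H93-H102. Returns `NULL` (with a `reason` attribute) when either
#' motif is absent, the span is empty, the downstream motif precedes the
#' upstream one, or the span contains a stop.
#'
#' @param aa Amino-acid sequence (character scalar).
#' @param upstreamMotif,downstreamMotifs Anchor motifs; the downstream
#'   default is exactly the two literal Val/Ile variants.
#' @return `list(aa=, span=)` with a 0-based half-open residue span, or
#'   a "none" sentinel (see [isNone()]).
#' @examples
#' extractCdrh3("XXDSATYYGCGKLLVTVSSXX")
#' @export
extractCdrh3 <- function(aa, upstreamMotif = .UPSTREAM_MOTIF,
                         downstreamMotifs = .DOWNSTREAM_MOTIFS) {
  stopifnot(nchar(upstreamMotif) > 0L, all(nchar(downstreamMotifs) > 0L))
  fail <- .none
  up <- regexpr(upstreamMotif, aa, fixed = TRUE)
  if (up == -1L) return(fail("no_upstream_motif"))
  from <- up + attr(up, "match.length")      # 1-based start of CDRH3
  downPos <- vapply(downstreamMotifs, function(m) {
    p <- regexpr(m, aa, fixed = TRUE)
    as.integer(p)
  }, integer(1))
  downPos <- downPos[downPos != -1L]
  if (!length(downPos)) return(fail("no_downstream_motif"))
  down <- min(downPos)
  if (down < from) return(fail("downstream_before_upstream"))
  if (down == from) return(fail("empty_span"))
  region <- substr(aa, from, down - 1L)
  if (grepl("*", region, fixed = TRUE)) return(fail("stop_in_cdrh3"))
  list(aa = region, span = c(from - 1L, down - 1L))
}

#' Select the reading frame and collect a CDRH3 from one read
#'
#' Translates the read in all three frames and extracts a motif-bounded,
#' stop-free CDRH3. Exactly one qualifying frame is required: reads
#' matching in zero frames, or ambiguously in several, are discarded with
#' a reason code, as are reads with `N` in the CDRH3 nucleotide span.
#'
#' @param nt Read nucleotide sequence.
#' @return `list(cdrh3_nt=, cdrh3_aa=, frame=)` on success, else a "none"
#'   sentinel whose reason code is one of `no_frame`, `ambiguous_frame`,
#'   `n_in_cdrh3` (see [isNone()]).
#' @export
collectCdrh3 <- function(nt) {
  nt <- as.character(nt)
  fail <- .none
  tr <- translateThreeFrames(nt)
  hits <- list()
  for (f in 0:2) {
    ex <- extractCdrh3(tr[[f + 1L]])
    if (!isNone(ex)) hits[[length(hits) + 1L]] <- c(ex, frame = f)
  }
  if (length(hits) == 0L) return(fail("no_frame"))
  if (length(hits) > 1L) return(fail("ambiguous_frame"))
  h <- hits[[1L]]
  f <- h$frame
  ntStart <- f + 3L * h$span[1L] + 1L       # 1-based
  ntSeq <- substr(nt, ntStart, ntStart + 3L * nchar(h$aa) - 1L)
  if (grepl("N", ntSeq, fixed = TRUE)) return(fail("n_in_cdrh3"))
  list(cdrh3_nt = ntSeq, cdrh3_aa = h$aa, frame = f)
}

#' Deduplicate CDRH3 records and count copies
#'
#' Exact nucleotide-level deduplication within one sample; output is
#' sorted by descending copy number, then lexicographic nucleotide
#' sequence.
#'
#' @param cdrs `data.frame` with columns `sample_barcode`, `cdrh3_nt`,
#'   `cdrh3_aa`, `frame` (one row per read).
#' @return `data.frame` with columns `sample_barcode`, `cdrh3_nt`,
#'   `cdrh3_aa`, `frame`, `copy_number`.
#' @export
dedupeAndCount <- function(cdrs) {
  cols <- c("sample_barcode", "cdrh3_nt", "cdrh3_aa", "frame")
  if (nrow(cdrs) == 0L) {
    out <- cdrs[, intersect(cols, names(cdrs)), drop = FALSE]
    out$copy_number <- integer(0)
    return(out)
  }
  if (length(unique(cdrs$sample_barcode)) != 1L)
    stop("dedupeAndCount expects records from a single sample barcode")
  tab <- table(cdrs$cdrh3_nt)
  first <- cdrs[!duplicated(cdrs$cdrh3_nt), cols, drop = FALSE]
  first$copy_number <- as.integer(tab[first$cdrh3_nt])
  ord <- order(-first$copy_number, first$cdrh3_nt)
  out <- first[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Process raw reads into a per-sample CDRH3 table
#'
#' Demultiplexes, translates, extracts and deduplicates in one call -
#' the computational chain applied to an Ion Torrent CDRH3 library.
#'
#' @inheritParams demultiplexReads
#' @param minCopies Drop unique CDRH3 observed fewer than this many times.
#' @return `list(cdr = data.frame, discards = named integer)` where
#'   `discards` tabulates per-read rejection reasons.
#' @export
processReads <- function(reads, barcodes, maxMismatch = 1L, minCopies = 1L) {
  bins <- demultiplexReads(reads, barcodes, maxMismatch)
  discards <- c(undetermined_barcode = length(bins$undetermined))
  perSample <- list()
  for (b in barcodes) {
    rows <- list()
    for (s in as.character(bins[[b]])) {
      hit <- collectCdrh3(s)
      if (isNone(hit)) {
        r <- noneReason(hit)
        discards[r] <- (if (r %in% names(discards)) discards[[r]] else 0L) + 1L
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_barcode = b, cdrh3_nt = hit$cdrh3_nt,
          cdrh3_aa = hit$cdrh3_aa, frame = hit$frame,
          stringsAsFactors = FALSE)
      }
    }
    tab <- if (length(rows)) dedupeAndCount(do.call(rbind, rows)) else
      dedupeAndCount(data.frame(sample_barcode = character(0),
                                cdrh3_nt = character(0),
                                cdrh3_aa = character(0),
                                frame = integer(0)))
    perSample[[b]] <- tab[tab$copy_number >= minCopies, , drop = FALSE]
  }
  cdr <- do.call(rbind, perSample)
  rownames(cdr) <- NULL
  list(cdr = cdr, discards = discards)
}

#' Theoretical V(D)J combinatorial diversity
#'
#' The product of segment counts: with the human complement of 55 V, 23 D
#' and 6 J heavy-chain segments this gives 7,590 combinations, against
#' roughly 10 x 10 x 4 for cattle - the paucity that drives bovine
#' reliance on somatic hypermutation. (Note the arithmetic for cattle,
#' 400, is smaller than the "approximately 4,000" usually quoted for the
#' bovine heavy-chain repertoire; the operation implements the plain
#' product.)
#'
#' @param v,d,j Segment counts (positive integers).
#' @return `v * d * j`.
#' @examples
#' theoreticalDiversity(55, 23, 6)
#' @export
theoreticalDiversity <- function(v, d, j) {
  for (x in list(v, d, j)) .assertCount(x, "segment count")
  as.numeric(v) * as.numeric(d) * as.numeric(j)
}
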