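# Ultralong CDRH3 classification and cysteine architecture profiling.

#' UltralongAnnotation: evidence that a CDRH3 is ultralong
#'
#' @slot isUltralong Classification flag.
#' @slot lengthNt CDRH3 nucleotide length.
#' @slot duplicationFound,duplicationOffsets Evidence for the duplicated
#'   V-tail hallmark: two non-overlapping (<= 1 mismatch by default)
#'   matches of the duplication probe; offsets are 0-based or `NA`.
#' @slot cysCount,cysPositions,cysPattern,parity Cysteine profile of the
#'   amino-acid sequence (0-based positions; spacing pattern such as
#'   `"C-x3-C"`; parity of the count).
#' @name UltralongAnnotation-class
#' @aliases UltralongAnnotation
#' @exportClass UltralongAnnotation
setClass("UltralongAnnotation",
  representation(
    isUltralong = "logical",
    lengthNt = "integer",
    duplicationFound = "logical",
    duplicationOffsets = "integer",
    cysCount = "integer",
    cysPositions = "integer",
    cysPattern = "character",
    parity = "character"
  )
)

setValidity("UltralongAnnotation", function(object) {
  msg <- character()
  if (object@cysCount != length(object@cysPositions))
    msg <- c(msg, "cysCount must equal length(cysPositions)")
  if (!(object@parity %in% c("even", "odd")))
    msg <- c(msg, "parity must be 'even' or 'odd'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "UltralongAnnotation", function(object) {
  cat(sprintf(
    "UltralongAnnotation: %s (%d nt), %d Cys (%s)%s\n",
    if (object@isUltralong) "ultralong" else "regular",
    object@lengthNt, object@cysCount, object@parity,
    if (object@duplicationFound) ", V-tail duplication found" else ""))
  if (nzchar(object@cysPattern))
    cat("  pattern: ", object@cysPattern, "\n", sep = "")
})

#' Cysteine profile of an amino-acid sequence
#'
#' @param aa Non-empty amino-acid sequence.
#' @return `list(cys_count, cys_positions (0-based), cys_pattern, parity)`.
#'   The pattern string lists inter-cysteine gaps, e.g. `"C-x3-C-x1-C"`;
#'   zero cysteines give an empty pattern and even parity.
#' @examples
#' cysteineProfile("ACGCA")
#' @export
cysteineProfile <- function(aa) {
  if (!nzchar(aa)) stop("aa must be non-empty")
  pos <- which(strsplit(aa, "")[[1]] == "C") - 1L
  n <- length(pos)
  pattern <- if (n == 0L) "" else if (n == 1L) "C" else
    paste0("C", paste0("-x", diff(pos) - 1L, "-C", collapse = ""))
  list(cys_count = n, cys_positions = pos, cys_pattern = pattern,
       parity = if (n %% 2L == 0L) "even" else "odd")
}

# Reconstruct 0-based positions from a spacing pattern and the first
# position (inverse of cysteineProfile's pattern string).
#' @noRd
.patternToPositions <- function(pattern, first) {
  if (!nzchar(pattern)) return(integer(0))
  gaps <- as.integer(regmatches(pattern, gregexpr("(?<=x)\\d+", pattern,
                                                  perl = TRUE))[[1]])
  cumsum(c(first, gaps + 1L))
}

#' Classify a CDRH3 as ultralong
#'
#' Length is the primary criterion and is strict: a CDRH3 is ultralong
#' when its nucleotide length exceeds `lengthThresholdNt` (default 90 bp).
#' Optionally the duplicated V-tail hallmark is also required: two
#' non-overlapping matches of `duplicationProbe` (at most
#' `maxProbeMismatch` mismatches each) within the CDRH3 nucleotide span.
#'
#' @param cdrh3Nt CDRH3 nucleotide sequence.
#' @param cdrh3Aa Matching amino-acid sequence (defaults to the frame-0
#'   translation of `cdrh3Nt`).
#' @param lengthThresholdNt Strict length threshold in nucleotides.
#' @param requireDuplication Require the duplication hallmark too?
#' @param duplicationProbe Probe sequence; mandatory when
#'   `requireDuplication = TRUE`, and defaults to the bundled synthetic
#'   duplication tail.
#' @param maxProbeMismatch Per-match mismatch tolerance (hypermutation may
#'   hit the probe).
#' @return An [UltralongAnnotation].
#' @examples
#' isUltralong(strrep("TGTGCA", 16))
#' @export
isUltralong <- function(cdrh3Nt, cdrh3Aa = NULL, lengthThresholdNt = 90L,
                        requireDuplication = FALSE,
                        duplicationProbe = NULL, maxProbeMismatch = 1L) {
  if (requireDuplication && (is.null(duplicationProbe) ||
                             !nzchar(duplicationProbe)))
    stop("requireDuplication = TRUE needs a non-empty duplicationProbe")
  if (is.null(cdrh3Aa)) {
    w <- (nchar(cdrh3Nt) %/% 3L) * 3L
    cdrh3Aa <- translateThreeFrames(substr(cdrh3Nt, 1L, w))[["frame0"]]
  }
  lengthNt <- nchar(cdrh3Nt)
  dupFound <- FALSE
  dupOffsets <- NA_integer_
  if (!is.null(duplicationProbe) && nzchar(duplicationProbe)) {
    m <- Biostrings::matchPattern(duplicationProbe,
                                  Biostrings::DNAString(cdrh3Nt),
                                  max.mismatch = maxProbeMismatch)
    # greedy left-to-right selection of non-overlapping matches
    sel <- integer(0)
    lastEnd <- 0L
    for (k in seq_along(m)) {
      if (IRanges::start(m)[k] > lastEnd) {
        sel <- c(sel, k)
        lastEnd <- IRanges::end(m)[k]
      }
    }
    if (length(sel) >= 2L) {
      dupFound <- TRUE
      dupOffsets <- IRanges::start(m)[sel[1:2]] - 1L
    }
  }
  isUl <- lengthNt > lengthThresholdNt
  if (requireDuplication) isUl <- isUl && dupFound
  prof <- cysteineProfile(cdrh3Aa)
  new("UltralongAnnotation",
      isUltralong = isUl, lengthNt = lengthNt,
      duplicationFound = dupFound, duplicationOffsets = dupOffsets,
      cysCount = prof$cys_count, cysPositions = prof$cys_positions,
      cysPattern = prof$cys_pattern, parity = prof$parity)
}

#' Annotate a CDRH3 table with ultralong and cysteine columns
#'
#' @param cdr CDRH3 table (as from [processReads()]).
#' @inheritParams isUltralong
#' @return The table with added columns `is_ultralong`, `length_nt`,
#'   `duplication_found`, `cys_count`, `cys_pattern`, `cys_parity`.
#' @export
annotateUltralong <- function(cdr, lengthThresholdNt = 90L,
                              requireDuplication = FALSE,
                              duplicationProbe = NULL,
                              maxProbeMismatch = 1L) {
  anns <- lapply(seq_len(nrow(cdr)), function(i)
    isUltralong(cdr$cdrh3_nt[i], cdr$cdrh3_aa[i], lengthThresholdNt,
                requireDuplication, duplicationProbe, maxProbeMismatch))
  cdr$is_ultralong <- vapply(anns, slot, logical(1), "isUltralong")
  cdr$length_nt <- vapply(anns, slot, integer(1), "lengthNt")
  cdr$duplication_found <- vapply(anns, slot, logical(1), "duplicationFound")
  cdr$cys_count <- vapply(anns, slot, integer(1), "cysCount")
  cdr$cys_pattern <- vapply(anns, slot, character(1), "cysPattern")
  cdr$cys_parity <- vapply(anns, slot, character(1), "parity")
  cdr
}

#' Cohort summary of ultralong classification and cysteine parity
#'
#' @param ann Annotated table from [annotateUltralong()].
#' @return `list(counts = data.frame(length_class, cys_count, parity, n),
#'   n_total, n_ultralong, ultralong_fraction)`; marginal totals equal the
#'   input size.
#' @export
cohortSummary <- function(ann) {
  if (nrow(ann) == 0L) stop("empty annotation table")
  lengthClass <- ifelse(ann$is_ultralong, "ultralong", "regular")
  counts <- as.data.frame(table(length_class = lengthClass,
                                cys_count = ann$cys_count,
                                parity = ann$cys_parity),
                          responseName = "n", stringsAsFactors = FALSE)
  counts <- counts[counts$n > 0L, , drop = FALSE]
  counts$cys_count <- as.integer(counts$cys_count)
  rownames(counts) <- NULL
  list(counts = counts,
       n_total = nrow(ann),
       n_ultralong = sum(ann$is_ultralong),
       ultralong_fraction = mean(ann$is_ultralong))
}

#' Percentage bookkeeping helpers
#'
#' `pctUltralong` reports an ultralong percentage at one decimal;
#' `hitRatePct` reports a screening hit rate at integer precision.
#'
#' @param nUltralong,nTotal,nHits,nScreened Counts.
#' @return A number (percentage), or `NA` when the denominator is zero.
#' @examples
#' pctUltralong(154, 3559)  # 4.3
#' hitRatePct(14, 52)       # 27
#' @export
pctUltralong <- function(nUltralong, nTotal) {
  if (nTotal == 0) return(NA_real_)
  round(100 * nUltralong / nTotal, 1L)
}

#' @rdname pctUltralong
#' @export
hitRatePct <- function(nHits, nScreened) {
  if (nScreened == 0) return(NA_real_)
  round(100 * nHits / nScreened)
}
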