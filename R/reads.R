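# Amplicon read emission: Ion-Torrent-style barcoded CDRH3 reads with a
# configurable substitution/homopolymer-indel error channel.

# Library architecture constants (sense strand):
#   A adaptor + 8-nt barcode + C + framework-3 primer + CDRH3 +
#   framework-4 locus + reverse-complemented trP1 adaptor.
# The forward primer's final two bases overlap the first CDRH3 codon (the
# conserved junction cysteine), so the CDRH3 starts "TG"; those two bases
# are primer-clamped and never mutated by the generator.
.ADAPTOR_A <- "CCATCTCATCCCTGCGTGTCTCCGACTCAG"
.ADAPTOR_P1 <- "CCTCTCTATGGGCAGTCGGTGAT"
.PRIMER_FWD <- "GGACTCGGCCACMTAYTACTG"   # translates ...DSATYY + "TG"
.F4_TEMPLATE <- "CTGRTCACCGTCTCGAGC"     # revcomp of reverse primer; L[VI]TVSS

# Expand IUPAC degeneracy uniformly at random (primer pools are mixtures).
#' @noRd
.expandIupac <- function(x) {
  ch <- strsplit(x, "")[[1]]
  ch[ch == "M"] <- sample(c("A", "C"), sum(ch == "M"), replace = TRUE)
  ch[ch == "Y"] <- sample(c("C", "T"), sum(ch == "Y"), replace = TRUE)
  ch[ch == "R"] <- sample(c("A", "G"), sum(ch == "R"), replace = TRUE)
  paste(ch, collapse = "")
}

# Substitutions at subRate per base; indels at indelRate, elevated by
# `homoMult` inside homopolymer runs (length >= 2). Insertions duplicate
# the base (the Ion-Torrent flow-call failure mode); deletions drop it.
#' @noRd
.injectErrors <- function(read, subRate, indelRate, homoMult) {
  if (subRate == 0 && indelRate == 0) return(read)
  b <- strsplit(read, "")[[1]]
  n <- length(b)
  sub <- runif(n) < subRate
  if (any(sub)) {
    for (i in which(sub)) b[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                                 b[i]), 1L)
  }
  if (indelRate > 0) {
    inRun <- c(FALSE, b[-1] == b[-n]) | c(b[-n] == b[-1], FALSE)
    rate <- ifelse(inRun, pmin(1, indelRate * homoMult), indelRate)
    ev <- runif(n) < rate
    if (any(ev)) {
      ins <- runif(n) < 0.5
      out <- character(0)
      for (i in seq_len(n)) {
        if (ev[i]) {
          if (ins[i]) out <- c(out, b[i], b[i])  # duplication
          # else deletion: emit nothing
        } else out <- c(out, b[i])
      }
      b <- out
    }
  }
  paste(b, collapse = "")
}

#' Emit barcoded amplicon reads from a truth table
#'
#' Every clone yields `copy_number` reads of the form
#' `adaptor + barcode + C + forward-primer expansion + CDRH3 +
#' framework-4 locus + trP1 adaptor`, with IUPAC-degenerate primer
#' positions expanded uniformly at random per read. Sequencing errors are
#' injected at the given substitution and indel rates, with the indel rate
#' multiplied by `homopolymerMultiplier` inside homopolymer runs. Base
#' qualities are constant Q30 placeholders.
#'
#' @param records Truth table from [simulateRepertoire()].
#' @param barcodes The full barcode sheet (distinct 8-nt sequences); the
#'   records' `sample_barcode` values must be among them.
#' @param subRate,indelRate Per-base error probabilities.
#' @param seed Integer seed; fixed seeds give byte-identical output.
#' @param homopolymerMultiplier Indel-rate multiplier in homopolymer runs.
#' @return A [Biostrings::QualityScaledDNAStringSet]; write with
#'   [writeFastq()].
#' @examples
#' tr <- simulateRepertoire(defaultGermlineSet(),
#'                          repertoireConfig(nClones = 5L, seed = 3L))
#' emitReads(tr, defaultBarcodes(), seed = 3L)
#' @export
emitReads <- function(records, barcodes, subRate = 0, indelRate = 0,
                      seed = 1L, homopolymerMultiplier = 5) {
  .assertDna(barcodes, "barcodes")
  if (any(nchar(barcodes) != 8L)) stop("barcodes must be 8 nt long")
  if (anyDuplicated(barcodes)) stop("barcode collision: barcodes must be distinct")
  if (subRate < 0 || indelRate < 0) stop("error rates must be >= 0")
  if (!all(records$sample_barcode %in% barcodes))
    stop("records carry barcodes absent from the barcode sheet")
  if (!all(startsWith(records$cdrh3_nt, "TG")))
    stop("CDRH3 sequences must start with the primer-clamped TG bases")
  set.seed(seed)
  seqs <- character(0)
  ids <- character(0)
  k <- 0L
  for (r in seq_len(nrow(records))) {
    for (d in seq_len(records$copy_number[r])) {
      k <- k + 1L
      read <- paste0(.ADAPTOR_A, records$sample_barcode[r], "C",
                     .expandIupac(.PRIMER_FWD),
                     substring(records$cdrh3_nt[r], 3L),
                     "CTG", .expandIupac(.F4_TEMPLATE),
                     .revcomp(.ADAPTOR_P1))
      seqs <- c(seqs, .injectErrors(read, subRate, indelRate,
                                    homopolymerMultiplier))
      ids <- c(ids, sprintf("read%06d %s", k, records$clone_id[r]))
    }
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  qual <- Biostrings::PhredQuality(vapply(nchar(seqs), function(n)
    paste(rep("?", n), collapse = ""), character(1)))  # "?" = Q30
  Biostrings::QualityScaledDNAStringSet(dna, qual)
}

#' Write / read FASTQ (Sanger Phred+33)
#'
#' Thin wrappers over Biostrings' FASTQ support. `readFastq` performs a
#' light structural validation so a malformed 4-line block is reported
#' with its record index.
#'
#' @param x A [Biostrings::QualityScaledDNAStringSet].
#' @param path FASTQ file path.
#' @export
writeFastq <- function(x, path) {
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' @rdname writeFastq
#' @export
readFastq <- function(path) {
  .checkFastq(path)
  Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
}

#' @noRd
.checkFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: truncated record ", length(lines) %/% 4L + 1L)
  if (length(lines)) {
    idx <- seq(1L, length(lines), by = 4L)
    badAt <- which(!startsWith(lines[idx], "@"))
    badPlus <- which(!startsWith(lines[idx + 2L], "+"))
    if (length(badAt))
      stop("malformed FASTQ record ", badAt[1L], ": missing '@' header")
    if (length(badPlus))
      stop("malformed FASTQ record ", badPlus[1L], ": missing '+' separator")
    badLen <- which(nchar(lines[idx + 1L]) != nchar(lines[idx + 3L]))
    if (length(badLen))
      stop("malformed FASTQ record ", badLen[1L],
           ": sequence/quality length mismatch")
  }
  invisible(TRUE)
}

#' Convert FASTQ to FASTA
#'
#' Order-preserving: identifiers are preserved up to the first whitespace
#' and qualities are dropped.
#'
#' @param fastqPath,fastaPath Input and output file paths.
#' @return Invisibly, the [Biostrings::DNAStringSet] written.
#' @export
fastqToFasta <- function(fastqPath, fastaPath) {
  s <- readFastq(fastqPath)
  out <- Biostrings::DNAStringSet(as.character(s))
  names(out) <- sub("\\s.*$", "", names(s))
  Biostrings::writeXStringSet(out, fastaPath)
  invisible(out)
}
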