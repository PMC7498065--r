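# Internal helpers shared across modules.

#' @noRd
.assertProb <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single probability in [0, 1]", call. = FALSE)
  invisible(x)
}

#' @noRd
.assertCount <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop(what, " must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

#' @noRd
.assertDna <- function(x, what) {
  if (!all(grepl("^[ACGT]+$", x)))
    stop(what, " must be over the alphabet {A,C,G,T}", call. = FALSE)
  invisible(x)
}

# Hamming distance between equal-length character scalars.
#' @noRd
.hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Deterministic md5 of a canonical JSON rendering; used for config hashes.
#' @noRd
.jsonHash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           null = "null")), tf)
  unname(tools::md5sum(tf))
}

# Reverse complement for plain character vectors.
#' @noRd
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
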