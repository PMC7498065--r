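# Synthetic clonotype-structured knob cohort: a stand-in for an
# antigen-enriched ultralong CDRH3 cohort with known family structure.

#' Simulate a clonotype-structured cohort of knob sequences
#'
#' Generates a cohort of amino-acid sequences with a planted clonotype
#' structure: `nClonotypes` families of clonally related sequences
#' (members derived from a common ancestor by point substitutions at
#' `withinMutation` of positions, keeping within-family identity well
#' above typical clustering thresholds) plus unrelated singletons, with
#' `clonotypeFraction` of all sequences belonging to families. This is a
#' synthetic stand-in for real antigen-enriched cohorts (whose raw
#' sequences are not deposited) used to exercise and validate the
#' clonotype clustering stage against known ground truth.
#'
#' @param nSequences Total cohort size.
#' @param nClonotypes Number of planted families (each of size >= 2).
#' @param clonotypeFraction Fraction of sequences belonging to families.
#' @param lengthRange Sequence length range (knob-domain scale).
#' @param withinMutation Per-position substitution probability applied to
#'   each family member relative to its ancestor.
#' @param seed Integer seed.
#' @return `data.frame(sequence, family)` where `family` is the planted
#'   family label (`NA` for singletons); sequences are unique.
#' @examples
#' coh <- simulateKnobCohort(40, 5, seed = 1L)
#' table(is.na(coh$family))
#' @export
simulateKnobCohort <- function(nSequences = 154L, nClonotypes = 20L,
                               clonotypeFraction = 0.5,
                               lengthRange = c(35L, 45L),
                               withinMutation = 0.06, seed = 1L) {
  stopifnot(nSequences >= 2L * nClonotypes)
  set.seed(seed)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  randomSeq <- function() {
    L <- sample(seq(lengthRange[1L], lengthRange[2L]), 1L)
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }
  mutate <- function(s) {
    b <- strsplit(s, "")[[1]]
    hit <- which(runif(length(b)) < withinMutation)
    for (i in hit) b[i] <- sample(setdiff(alphabet, b[i]), 1L)
    paste(b, collapse = "")
  }
  nFam <- round(nSequences * clonotypeFraction)
  sizes <- rep(2L, nClonotypes)
  k <- 1L
  while (sum(sizes) < nFam) {
    sizes[k] <- sizes[k] + 1L
    k <- if (k == nClonotypes) 1L else k + 1L
  }
  seqs <- character(0)
  fam <- character(0)
  for (f in seq_len(nClonotypes)) {
    anc <- randomSeq()
    for (m in seq_len(sizes[f])) {
      repeat {
        s <- mutate(anc)
        if (!(s %in% seqs)) break
      }
      seqs <- c(seqs, s)
      fam <- c(fam, sprintf("family%02d", f))
    }
  }
  nSing <- nSequences - sum(sizes)
  for (m in seq_len(nSing)) {
    repeat {
      s <- randomSeq()
      if (!(s %in% seqs)) break
    }
    seqs <- c(seqs, s)
    fam <- c(fam, NA_character_)
  }
  data.frame(sequence = seqs, family = fam, stringsAsFactors = FALSE)
}
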