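# Clonotyping: percent identity from one optimal global alignment, and
# single-linkage clustering at a homology threshold.

# Identity scoring scheme: match +1, mismatch 0, gap open -10, gap
# extend -1. Gapped columns count against identity (length differences
# between clonally related CDRH3 must penalise).
#' @noRd
.identityMatrix <- function() {
  letters <- strsplit("ACDEFGHIKLMNPQRSTVWYX*", "")[[1]]
  m <- diag(1, length(letters))
  dimnames(m) <- list(letters, letters)
  m["X", "X"] <- 0
  m
}

#' Percent identity between two amino-acid sequences
#'
#' Computed from one optimal Needleman-Wunsch global alignment
#' (match +1, mismatch 0, gap open -10, gap extend -1):
#' `identity = 100 * matches / alignment columns`. The argument pair is
#' ordered canonically before aligning, so the result is symmetric.
#'
#' @param a,b Non-empty amino-acid sequences.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwiseIdentity("AAAA", "AAAT")  # 75
#' @export
pairwiseIdentity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .identityMatrix(),
    gapOpening = 10, gapExtension = 1, type = "global")
  # columns = residues of both sequences minus doubly-occupied columns
  columns <- nchar(a) + nchar(b) -
    (Biostrings::nmatch(aln) + Biostrings::nmismatch(aln))
  100 * Biostrings::nmatch(aln) / columns
}

# All-pairs identity matrix (symmetric, 100 on the diagonal). Pairs are
# aligned in canonical (lexicographic) order, batched per subject so the
# alignment engine vectorises over patterns; results agree with
# pairwiseIdentity() pair by pair.
#' @noRd
.identityAllPairs <- function(seqs) {
  n <- length(seqs)
  m <- matrix(100, n, n)
  if (n < 2L) return(m)
  ord <- order(seqs)
  sorted <- seqs[ord]
  sub <- .identityMatrix()
  for (j in 2L:n) {
    pats <- Biostrings::AAStringSet(sorted[seq_len(j - 1L)])
    aln <- Biostrings::pairwiseAlignment(
      pats, Biostrings::AAString(sorted[j]),
      substitutionMatrix = sub, gapOpening = 10, gapExtension = 1,
      type = "global")
    cols <- nchar(sorted[seq_len(j - 1L)]) + nchar(sorted[j]) -
      (Biostrings::nmatch(aln) + Biostrings::nmismatch(aln))
    idj <- 100 * Biostrings::nmatch(aln) / cols
    m[ord[seq_len(j - 1L)], ord[j]] <- idj
    m[ord[j], ord[seq_len(j - 1L)]] <- idj
  }
  m
}

#' Cluster sequences into clonotypes by percent identity
#'
#' Single-linkage clusters are the connected components of the graph whose
#' edges join pairs meeting the identity threshold (`mode = "geq"` for
#' `>=`, `"gt"` for `>`). Components are independent of input order; the
#' output ordering is deterministic (cluster size descending, then
#' representative sequence).
#'
#' Each cluster's representative is its highest-copy member, ties broken
#' by lexicographically smallest sequence.
#'
#' @param seqs Character vector of amino-acid sequences (unique).
#' @param thresholdPct Identity threshold in (0, 100].
#' @param mode `"geq"` (default, >= threshold) or `"gt"` (> threshold).
#' @param copyNumber Optional per-sequence copy numbers (default 1).
#' @return `data.frame(clonotype_id, member, representative, size)`, one
#'   row per member sequence.
#' @examples
#' clusterClonotypes(c("AAAA", "AAAT", "WWWW"), thresholdPct = 75)
#' @export
clusterClonotypes <- function(seqs, thresholdPct = 75, mode = c("geq", "gt"),
                              copyNumber = NULL) {
  mode <- match.arg(mode)
  if (thresholdPct <= 0 || thresholdPct > 100)
    stop("thresholdPct must lie in (0, 100]")
  if (length(seqs) == 0L)
    return(data.frame(clonotype_id = character(0), member = character(0),
                      representative = logical(0), size = integer(0)))
  if (anyDuplicated(seqs)) stop("seqs must be unique")
  if (is.null(copyNumber)) copyNumber <- rep(1L, length(seqs))
  stopifnot(length(copyNumber) == length(seqs))

  idm <- .identityAllPairs(seqs)
  keep <- if (mode == "geq") idm >= thresholdPct else idm > thresholdPct
  # connected components via igraph
  n <- length(seqs)
  edges <- which(keep & upper.tri(keep), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1L]),
               to = as.character(edges[, 2L])),
    directed = FALSE, vertices = data.frame(name = as.character(seq_len(n))))
  comp <- igraph::components(g)$membership[as.character(seq_len(n))]

  reps <- vapply(split(seq_len(n), comp), function(ix) {
    ix <- ix[order(-copyNumber[ix], seqs[ix])]
    seqs[ix[1L]]
  }, character(1))
  sizes <- as.integer(table(comp)[names(reps)])
  ord <- order(-sizes, reps)
  out <- do.call(rbind, lapply(seq_along(ord), function(k) {
    cid <- names(reps)[ord[k]]
    ix <- which(comp == as.integer(cid))
    ix <- ix[order(seqs[ix])]
    data.frame(clonotype_id = sprintf("CT%03d", k),
               member = seqs[ix],
               representative = seqs[ix] == reps[[cid]],
               size = length(ix),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Summarise clonotype structure
#'
#' A cluster counts as a clonotype when it has at least
#' `minMembersForClonotype` members; smaller clusters of size one are
#' singletons.
#'
#' @param clusters Output of [clusterClonotypes()].
#' @param minMembersForClonotype Minimum cluster size for a clonotype.
#' @return `list(n_clonotypes, n_singletons, fraction_in_clonotypes)`.
#' @examples
#' cl <- clusterClonotypes(c("AAAA", "AAAT", "WWWW"))
#' clonotypeSummary(cl)
#' @export
clonotypeSummary <- function(clusters, minMembersForClonotype = 2L) {
  if (nrow(clusters) == 0L)
    return(list(n_clonotypes = 0L, n_singletons = 0L,
                fraction_in_clonotypes = NA_real_))
  sizes <- vapply(split(clusters$size, clusters$clonotype_id), `[`,
                  integer(1), 1L)
  inCt <- sizes >= minMembersForClonotype
  list(n_clonotypes = sum(inCt),
       n_singletons = sum(sizes == 1L),
       fraction_in_clonotypes = sum(sizes[inCt]) / sum(sizes))
}
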