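# Synthetic repertoire generation: ground-truthed CDRH3 clones with
# cysteine-biased somatic hypermutation.

#' RepertoireConfig: parameters of the synthetic repertoire
#'
#' @slot nClones Number of clones to simulate.
#' @slot ultralongFraction Probability that a clone is ultralong.
#' @slot shmRate Per-nucleotide substitution probability of the somatic
#'   hypermutation model, applied across the CDRH3 (the two primer-clamped
#'   leading bases excepted).
#' @slot cysBias Multiplier (>= 1) on substitutions that convert a
#'   Gly/Tyr/Ser codon into a cysteine codon (TGT/TGC) by a single change -
#'   the mechanism that enriches knob cores in cysteines.
#' @slot cloneSizeProb Geometric success probability for copy numbers;
#'   copy_number ~ 1 + Geom(cloneSizeProb).
#' @slot seed Integer seed; identical seeds give bit-identical repertoires.
#'
#' @name RepertoireConfig-class
#' @aliases RepertoireConfig
#' @exportClass RepertoireConfig
setClass("RepertoireConfig",
  representation(
    nClones = "integer",
    ultralongFraction = "numeric",
    shmRate = "numeric",
    cysBias = "numeric",
    cloneSizeProb = "numeric",
    seed = "integer"
  )
)

setValidity("RepertoireConfig", function(object) {
  msg <- character()
  if (object@nClones < 1L) msg <- c(msg, "nClones must be >= 1")
  for (nm in c("ultralongFraction", "shmRate"))
    if (slot(object, nm) < 0 || slot(object, nm) > 1)
      msg <- c(msg, paste0(nm, " must lie in [0, 1]"))
  if (object@cysBias < 1) msg <- c(msg, "cysBias must be >= 1")
  if (object@cloneSizeProb <= 0 || object@cloneSizeProb > 1)
    msg <- c(msg, "cloneSizeProb must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn RepertoireConfig-class Constructor with study defaults: a
#'   naive-repertoire ultralong fraction of 0.10, a 1% per-site
#'   hypermutation load, a 5x cysteine-conversion bias and geometric clone
#'   sizes with mean ~3.
#' @param nClones,ultralongFraction,shmRate,cysBias,cloneSizeProb,seed See
#'   slots.
#' @export
repertoireConfig <- function(nClones = 500L, ultralongFraction = 0.10,
                             shmRate = 0.01, cysBias = 5,
                             cloneSizeProb = 0.3, seed = 1L) {
  .assertProb(ultralongFraction, "ultralongFraction")
  .assertProb(shmRate, "shmRate")
  new("RepertoireConfig",
      nClones = .assertCount(nClones, "nClones"),
      ultralongFraction = ultralongFraction,
      shmRate = shmRate,
      cysBias = as.numeric(cysBias),
      cloneSizeProb = as.numeric(cloneSizeProb),
      seed = .assertCount(seed, "seed", min = 0L))
}

setMethod("show", "RepertoireConfig", function(object) {
  cat(sprintf(paste0(
    "RepertoireConfig: %d clones, ultralong fraction %.3g, ",
    "SHM rate %.3g (Cys bias %.3g), clone-size p %.3g, seed %d\n"),
    object@nClones, object@ultralongFraction, object@shmRate,
    object@cysBias, object@cloneSizeProb, object@seed))
})

# Codon-aware SHM: independent per-site substitutions at rate `rate`; at
# Gly/Tyr/Ser codons, a substitution whose result is TGT/TGC gets weight
# `cysBias` against weight 1 for the other targets. `protect` gives 1-based
# positions (the primer-clamped bases) never mutated.
#' @noRd
.shmMutate <- function(nt, rate, cysBias, protect = integer()) {
  if (rate == 0) return(nt)
  bases <- strsplit(nt, "")[[1]]
  n <- length(bases)
  hit <- which(runif(n) < rate)
  hit <- setdiff(hit, protect)
  if (!length(hit)) return(nt)
  for (i in hit) {
    codonIdx <- ((i - 1L) %/% 3L)
    cStart <- codonIdx * 3L + 1L
    codon <- bases[cStart:(cStart + 2L)]
    aa <- .translateFast(paste(codon, collapse = ""))
    alts <- setdiff(c("A", "C", "G", "T"), bases[i])
    w <- rep(1, 3)
    if (aa %in% c("G", "Y", "S")) {
      for (k in seq_along(alts)) {
        cand <- codon
        cand[i - cStart + 1L] <- alts[k]
        if (paste(cand, collapse = "") %in% c("TGT", "TGC"))
          w[k] <- cysBias
      }
    }
    bases[i] <- sample(alts, 1L, prob = w / sum(w))
  }
  paste(bases, collapse = "")
}

#' Default sample barcodes
#'
#' Two maximally separated 8-mers (Hamming distance 8), mirroring the two
#' lymph-node samples sequenced per campaign.
#' @return Character vector of 8-nt barcodes.
#' @export
defaultBarcodes <- function() c("ACGTACGT", "TGCATGCA")

#' Simulate a ground-truthed CDRH3 repertoire
#'
#' Draws `nClones` clones. Each clone is flagged ultralong with probability
#' `ultralongFraction`. Regular clones are V + D + J germline
#' concatenations; ultralong clones are V + 2x duplication tail +
#' knob core (IGHD8-2 role) + stalk-bearing J, so they carry both the
#' length and the V-tail duplication hallmarks. Somatic hypermutation is
#' then applied per [RepertoireConfig]. Clones whose mutated CDRH3 acquires
#' a stop codon or an extraction-anchor motif are resampled (keeping their
#' ultralong flag): only productive rearrangements are observed in an IgG
#' amplicon library. Distinct clones may share a nucleotide sequence
#' (there are finitely many unmutated rearrangements); downstream
#' deduplication merges them, so recovery is assessed on per-sample unique
#' sequences and summed copy numbers.
#'
#' The planted knob span is structural: it starts at the residue
#' immediately preceding the first knob-core cysteine (whose position is
#' known exactly because substitutions preserve coordinates) and ends
#' before the first aromatic-initial aromatic/aliphatic alternation of
#' the descending stalk on the final (mutated) sequence. Annotation must
#' rediscover the cysteine positions by alignment, which is what recovery
#' tests exercise.
#'
#' @param germlines A [GermlineSet].
#' @param config A [RepertoireConfig].
#' @param barcodes Sample barcodes to assign clones to (8-nt, distinct).
#' @return A `data.frame` truth table with columns `clone_id`, `v_name`,
#'   `d_name`, `j_name`, `cdrh3_nt`, `cdrh3_aa`, `is_ultralong`,
#'   `knob_start`, `knob_end` (0-based half-open within the amino-acid
#'   CDRH3; `NA` for regular clones), `sample_barcode`, `copy_number`.
#' @examples
#' tr <- simulateRepertoire(defaultGermlineSet(),
#'                          repertoireConfig(nClones = 20L, seed = 7L))
#' table(tr$is_ultralong)
#' @export
simulateRepertoire <- function(germlines, config,
                               barcodes = defaultBarcodes()) {
  stopifnot(is(germlines, "GermlineSet"), is(config, "RepertoireConfig"))
  validObject(germlines)
  validObject(config)
  .assertDna(barcodes, "barcodes")
  if (anyDuplicated(barcodes)) stop("barcodes must be distinct")

  set.seed(config@seed)
  vs <- as.character(germlines@vSegments)
  ds <- as.character(germlines@dSegments)
  js <- as.character(germlines@jSegments)
  coreName <- germlines@ighd82Name
  regularD <- setdiff(names(ds), coreName)
  if (!length(regularD)) stop("need at least one non-core D segment")
  dup <- germlines@ighv17Tail
  coreAa <- ultralongCoreAa(germlines)
  coreCys <- which(strsplit(coreAa, "")[[1]] == "C") - 1L  # 0-based

  # J segments able to carry a descending stalk (aromatic-initial
  # alternation of length >= 3 in their translation)
  jAa <- vapply(js, .translateFast, character(1))
  stalkJ <- names(js)[vapply(jAa, function(a)
    !is.na(.firstAlternationStart(a, -1L)), logical(1))]
  if (!length(stalkJ))
    stop("no J segment can form a descending stalk (aromatic-aliphatic ",
         "alternation of length >= 3)")

  n <- config@nClones
  isUl <- runif(n) < config@ultralongFraction
  motifRx <- "DSATYY|LLVTVSS|LLITVSS"
  rows <- vector("list", n)
  pick1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  for (i in seq_len(n)) {
    for (attempt in 1:100) {
      vn <- pick1(names(vs))
      if (isUl[i]) {
        dn <- coreName
        jn <- pick1(stalkJ)
        nt0 <- paste0(vs[[vn]], dup, dup, ds[[dn]], js[[jn]])
        coreStartAa <- (nchar(vs[[vn]]) + 2L * nchar(dup)) %/% 3L
      } else {
        dn <- pick1(regularD)
        jn <- pick1(names(js))
        nt0 <- paste0(vs[[vn]], ds[[dn]], js[[jn]])
        coreStartAa <- NA_integer_
      }
      nt <- .shmMutate(nt0, config@shmRate, config@cysBias, protect = 1:2)
      aa <- .translateFast(nt)
      if (grepl("\\*", aa) || grepl(motifRx, aa)) next
      if (isUl[i]) {
        # boundaries planted from privileged knowledge of where the core
        # landed: SHM preserves coordinates, so the germline cysteine
        # positions are known exactly; the C-terminal scan runs on the
        # mutated sequence, as annotation will
        firstCys <- coreStartAa + coreCys[1L]
        lastCys <- coreStartAa + coreCys[length(coreCys)]
        ks <- firstCys - 1L
        ke <- .knobEndFromScan(aa, lastCys)
      } else {
        ks <- NA_integer_
        ke <- NA_integer_
      }
      rows[[i]] <- data.frame(
        clone_id = sprintf("clone%04d", i),
        v_name = vn, d_name = dn, j_name = jn,
        cdrh3_nt = nt, cdrh3_aa = aa,
        is_ultralong = isUl[i],
        knob_start = ks, knob_end = ke,
        sample_barcode = sample(barcodes, 1L),
        copy_number = rgeom(1L, config@cloneSizeProb) + 1L,
        stringsAsFactors = FALSE)
      break
    }
    if (is.null(rows[[i]]))
      stop("failed to generate a valid clone after 100 attempts")
  }
  do.call(rbind, rows)
}
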