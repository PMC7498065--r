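# Peptide mass prediction: elemental formulas, disulphide correction,
# charge-state m/z and aggregated isotope envelopes.
#
# Constants are pinned explicitly (monoisotopic masses from the standard
# residue composition table; isotope abundances from IUPAC representative
# values) because downstream matching against vendor LC/MS software
# depends on them being stated.

.ELEMENTS <- c("C", "H", "N", "O", "S")

# residue formulas (residue = amino acid minus one water)
.RESIDUE_FORMULA <- matrix(c(
  # C   H   N  O  S
    3,  5,  1, 1, 0,  # A
    6, 12,  4, 1, 0,  # R
    4,  6,  2, 2, 0,  # N
    4,  5,  1, 3, 0,  # D
    3,  5,  1, 1, 1,  # C
    5,  8,  2, 2, 0,  # Q
    5,  7,  1, 3, 0,  # E
    2,  3,  1, 1, 0,  # G
    6,  7,  3, 1, 0,  # H
    6, 11,  1, 1, 0,  # I
    6, 11,  1, 1, 0,  # L
    6, 12,  2, 1, 0,  # K
    5,  9,  1, 1, 1,  # M
    9,  9,  1, 1, 0,  # F
    5,  7,  1, 1, 0,  # P
    3,  5,  1, 2, 0,  # S
    4,  7,  1, 2, 0,  # T
   11, 10,  2, 1, 0,  # W
    9,  9,  1, 2, 0,  # Y
    5,  9,  1, 1, 0   # V
), ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                    "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                  .ELEMENTS))

.MONO_MASS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                O = 15.9949146196, S = 31.97207100)
.AVG_MASS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
.PROTON_MASS <- 1.00727646
.NEUTRON_MASS <- 1.00866491588

# per-element isotope distributions as (extra neutrons -> abundance)
.ISOTOPES <- list(
  C = c(`0` = 0.9893, `1` = 0.0107),
  H = c(`0` = 0.999885, `1` = 0.000115),
  N = c(`0` = 0.99636, `1` = 0.00364),
  O = c(`0` = 0.99757, `1` = 0.00038, `2` = 0.00205),
  S = c(`0` = 0.9499, `1` = 0.0075, `2` = 0.0425, `4` = 0.0001)
)

#' Elemental formula of a peptide
#'
#' Sum of residue formulas plus one water, over the CHNOS elements.
#'
#' @param aa Amino-acid sequence over the 20 standard residues.
#' @return Named integer vector with elements `C`, `H`, `N`, `O`, `S`.
#' @examples
#' peptideFormula("G")   # glycine: C2 H5 N O2
#' @export
peptideFormula <- function(aa) {
  res <- strsplit(aa, "")[[1]]
  bad <- which(!(res %in% rownames(.RESIDUE_FORMULA)))
  if (length(bad))
    stop("non-standard residue '", res[bad[1L]], "' at position ", bad[1L])
  f <- colSums(.RESIDUE_FORMULA[res, , drop = FALSE])
  f[["H"]] <- f[["H"]] + 2L
  f[["O"]] <- f[["O"]] + 1L
  storage.mode(f) <- "integer"
  f
}

#' Apply disulphide-bond mass correction to a formula
#'
#' Each disulphide bond removes two hydrogens (2 x 1.00782503 Da of
#' monoisotopic mass).
#'
#' @param formula Named element counts (as from [peptideFormula()]).
#' @param nDisulphides Number of bonds.
#' @return Corrected formula.
#' @export
applyDisulphides <- function(formula, nDisulphides) {
  n <- .assertCount(nDisulphides, "nDisulphides", min = 0L)
  if (formula[["H"]] < 2L * n)
    stop("insufficient hydrogens for ", n, " disulphide bond(s)")
  formula[["H"]] <- formula[["H"]] - 2L * n
  formula
}

#' Monoisotopic and average mass of a formula
#'
#' @param formula Named element counts.
#' @return A single mass in Da.
#' @export
monoisotopicMass <- function(formula)
  sum(.MONO_MASS[names(formula)] * formula)

#' @rdname monoisotopicMass
#' @export
averageMass <- function(formula)
  sum(.AVG_MASS[names(formula)] * formula)

#' m/z of a charge state
#'
#' `(M + z * 1.00727646) / z` for a protonated positive ion.
#'
#' @param monoMass Neutral monoisotopic mass in Da.
#' @param z Charge (>= 1).
#' @return m/z.
#' @examples
#' chargeStateMz(4000, 4)
#' @export
chargeStateMz <- function(monoMass, z) {
  if (any(z < 1L)) stop("z must be >= 1")
  (monoMass + z * .PROTON_MASS) / z
}

# exact n-atom isotope distribution by repeated convolution of the
# single-atom distribution over neutron counts
#' @noRd
.elementDistribution <- function(element, n) {
  single <- .ISOTOPES[[element]]
  offsets <- as.integer(names(single))
  base <- numeric(max(offsets) + 1L)
  base[offsets + 1L] <- single
  out <- 1
  left <- n
  pow <- base
  while (left > 0L) {       # binary exponentiation of the polynomial
    if (left %% 2L == 1L) out <- convolve(out, rev(pow), type = "open")
    left <- left %/% 2L
    if (left > 0L) pow <- convolve(pow, rev(pow), type = "open")
    out[out < 0] <- 0       # FFT round-off
    pow[pow < 0] <- 0
  }
  out
}

#' Aggregated isotope envelope of a formula at a charge state
#'
#' Computes the isotopologue distribution by iterative convolution of
#' per-element isotope distributions (indexed by extra neutron count),
#' normalises to a maximum abundance of 1, and truncates the tail below
#' `cutoff`. Peaks are spaced one neutron mass / z apart starting at the
#' monoisotopic peak, which is always the first row.
#'
#' @param formula Named element counts.
#' @param z Charge state.
#' @param cutoff Relative-abundance truncation threshold.
#' @return `data.frame(mz, abundance)`.
#' @examples
#' isotopeEnvelope(c(C = 1L, H = 0L, N = 0L, O = 0L, S = 0L), z = 1)
#' @export
isotopeEnvelope <- function(formula, z = 1L, cutoff = 1e-4) {
  if (z < 1L) stop("z must be >= 1")
  dist <- 1
  for (el in names(formula)) {
    if (formula[[el]] > 0L) {
      dist <- convolve(dist, rev(.elementDistribution(el, formula[[el]])),
                       type = "open")
      dist[dist < 0] <- 0
    }
  }
  dist <- dist / max(dist)
  lastKeep <- max(which(dist >= cutoff))
  dist <- dist[seq_len(lastKeep)]
  mono <- monoisotopicMass(formula)
  mz <- (mono + (seq_along(dist) - 1L) * .NEUTRON_MASS + z * .PROTON_MASS) / z
  data.frame(mz = mz, abundance = dist)
}

#' MassPrediction: full mass report for a peptide
#'
#' @slot peptideAa The peptide sequence.
#' @slot nDisulphides Number of disulphide bonds assumed.
#' @slot monoisotopicMass,averageMass Neutral masses in Da (disulphide
#'   corrected).
#' @slot chargeStates Named numeric: m/z per charge `z1`, `z2`, ...
#' @slot envelopes Named list of `data.frame(mz, abundance)` per charge.
#' @name MassPrediction-class
#' @aliases MassPrediction
#' @exportClass MassPrediction
setClass("MassPrediction",
  representation(
    peptideAa = "character",
    nDisulphides = "integer",
    monoisotopicMass = "numeric",
    averageMass = "numeric",
    chargeStates = "numeric",
    envelopes = "list"
  )
)

setValidity("MassPrediction", function(object) {
  msg <- character()
  if (object@monoisotopicMass > object@averageMass)
    msg <- c(msg, "monoisotopic mass must not exceed average mass")
  if (length(object@chargeStates) > 1L &&
      any(diff(object@chargeStates) >= 0))
    msg <- c(msg, "m/z must be strictly decreasing in z")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MassPrediction", function(object) {
  cat(sprintf(
    "MassPrediction: %d aa, %d S-S, mono %.4f Da, avg %.2f Da\n",
    nchar(object@peptideAa), object@nDisulphides,
    object@monoisotopicMass, object@averageMass))
  cat("  m/z:", paste(sprintf("%s %.4f", names(object@chargeStates),
                              object@chargeStates), collapse = ", "), "\n")
})

#' Predict masses, charge states and envelopes for a knob peptide
#'
#' By default all cysteines are assumed oxidised in pairs
#' (`nDisulphides = floor(nCys / 2)`), matching the fully bonded
#' interpretation used when matching LC/MS spectra of purified knob
#' domains.
#'
#' @param aa Peptide amino-acid sequence.
#' @param nDisulphides Number of disulphide bonds; `NULL` for the
#'   all-paired default.
#' @param charges Charge states to report (the 4+ state is the usual
#'   reference for knob-domain envelopes).
#' @return A [MassPrediction].
#' @examples
#' massPrediction("CAGTCPDGYC")
#' @export
massPrediction <- function(aa, nDisulphides = NULL, charges = 1:6) {
  nCys <- sum(strsplit(aa, "")[[1]] == "C")
  if (is.null(nDisulphides)) nDisulphides <- nCys %/% 2L
  if (2L * nDisulphides > nCys)
    stop("nDisulphides exceeds the available cysteine pairs")
  f <- applyDisulphides(peptideFormula(aa), nDisulphides)
  mono <- monoisotopicMass(f)
  mz <- vapply(charges, function(z) chargeStateMz(mono, z), numeric(1))
  names(mz) <- paste0("z", charges)
  env <- lapply(charges, function(z) isotopeEnvelope(f, z))
  names(env) <- paste0("z", charges)
  new("MassPrediction",
      peptideAa = aa, nDisulphides = as.integer(nDisulphides),
      monoisotopicMass = mono, averageMass = averageMass(f),
      chargeStates = mz, envelopes = env)
}
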