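# Independent oracles used across the suite. Each re-derives a quantity
# by a route disjoint from the package implementation: a hand-written
# codon table, exhaustive alignment enumeration, published residue
# masses, closed-form multinomial isotopologue enumeration, breadth-first
# graph components and numeric ODE integration.

# -- translation ------------------------------------------------------------

# standard genetic code, written out by hand (independent of
# Biostrings::GENETIC_CODE)
.ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracleTranslate <- function(nt, frame = 0L) {
  n <- nchar(nt)
  w <- ((n - frame) %/% 3L) * 3L
  if (w < 3L) return("")
  sub <- substr(nt, frame + 1L, frame + w)
  codons <- substring(sub, seq(1L, w - 2L, 3L), seq(3L, w, 3L))
  aa <- unname(.ORACLE_CODONS[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# -- alignment --------------------------------------------------------------

# Exhaustive enumeration of every global alignment of two short
# sequences under match +1 / mismatch 0 / gap of length L costing
# 10 + L. Returns the optimal score and the set of identity values
# attained by optimal alignments.
oracleAlignmentIdentities <- function(a, b, open = 10, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  best <- new.env()
  best$score <- -Inf
  best$ids <- numeric(0)
  rec <- function(i, j, score, matches, cols, lastGap) {
    # prune: remaining best gain is min(remaining) matches
    if (score + min(la - i, lb - j) < best$score - 1e-9) return(invisible())
    if (i == la && j == lb) {
      if (score > best$score + 1e-9) {
        best$score <- score
        best$ids <- numeric(0)
      }
      if (abs(score - best$score) <= 1e-9)
        best$ids <- unique(c(best$ids, 100 * matches / cols))
      return(invisible())
    }
    if (i < la && j < lb) {
      m <- if (av[i + 1L] == bv[j + 1L]) 1 else 0
      rec(i + 1L, j + 1L, score + m, matches + m, cols + 1L, 0L)
    }
    if (i < la) {  # gap in b
      pen <- if (lastGap == 1L) ext else open + ext
      rec(i + 1L, j, score - pen, matches, cols + 1L, 1L)
    }
    if (j < lb) {  # gap in a
      pen <- if (lastGap == 2L) ext else open + ext
      rec(i, j + 1L, score - pen, matches, cols + 1L, 2L)
    }
  }
  rec(0L, 0L, 0, 0L, 0L, 0L)
  list(score = best$score, identities = best$ids)
}

# -- peptide masses ---------------------------------------------------------

# published monoisotopic residue masses (Da)
.ORACLE_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
.ORACLE_WATER <- 18.0105646
.ORACLE_H <- 1.00782503

oraclePeptideMass <- function(aa, nDisulphides = 0L) {
  res <- strsplit(aa, "")[[1]]
  sum(.ORACLE_RESIDUE_MASS[res]) + .ORACLE_WATER -
    2 * nDisulphides * .ORACLE_H
}

# -- isotope envelopes ------------------------------------------------------

# closed-form per-element neutron-count distributions (dbinom /
# dmultinom), combined across elements by direct enumeration
.ORACLE_ISO <- list(
  C = list(p = c(0.9893, 0.0107), shift = c(0L, 1L)),
  H = list(p = c(0.999885, 0.000115), shift = c(0L, 1L)),
  N = list(p = c(0.99636, 0.00364), shift = c(0L, 1L)),
  O = list(p = c(0.99757, 0.00038, 0.00205), shift = c(0L, 1L, 2L)),
  S = list(p = c(0.9499, 0.0075, 0.0425, 0.0001), shift = c(0L, 1L, 2L, 4L)))

.oracleElementDist <- function(el, n, maxK = 60L) {
  iso <- .ORACLE_ISO[[el]]
  k <- length(iso$p)
  out <- numeric(maxK + 1L)
  if (k == 2L) {
    for (j in 0:min(n, maxK)) {
      sh <- j * iso$shift[2L]
      if (sh <= maxK)
        out[sh + 1L] <- out[sh + 1L] + dbinom(j, n, iso$p[2L])
    }
  } else {
    # enumerate heavy-isotope counts jointly
    heavy <- k - 1L
    grid <- expand.grid(rep(list(0:min(n, 30L)), heavy))
    for (r in seq_len(nrow(grid))) {
      cnt <- as.integer(grid[r, ])
      if (sum(cnt) > n) next
      sh <- sum(cnt * iso$shift[-1L])
      if (sh > maxK) next
      pr <- dmultinom(c(n - sum(cnt), cnt), prob = iso$p)
      out[sh + 1L] <- out[sh + 1L] + pr
    }
  }
  out
}

oracleEnvelope <- function(formula, maxK = 30L) {
  r <- c(1, numeric(maxK))
  for (el in names(formula)) {
    n <- formula[[el]]
    if (n == 0L) next
    v <- .oracleElementDist(el, n, maxK)
    rn <- numeric(maxK + 1L)
    for (kk in 0:maxK) {
      # direct sum over partitions of kk between r and v
      rn[kk + 1L] <- sum(r[seq_len(kk + 1L)] * v[(kk + 1L):1L])
    }
    r <- rn
  }
  r / max(r)
}

# -- clustering -------------------------------------------------------------

# breadth-first connected components over the thresholded identity graph
oracleComponents <- function(seqs, thresholdPct, mode = "geq") {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      id <- pairwiseIdentity(seqs[i], seqs[j])
      adj[i, j] <- if (mode == "geq") id >= thresholdPct else id > thresholdPct
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  # partition as a canonical set of member sets
  parts <- lapply(split(seqs, comp), sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1L))])
}

partitionOf <- function(clusters) {
  parts <- lapply(split(clusters$member, clusters$clonotype_id), sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1L))])
}

# -- kinetics ---------------------------------------------------------------

# fixed-step RK4 integration of dR/dt = kon C (Rmax - R) - koff R over
# the protocol's segments
oracleSckTrace <- function(kon, koff, Rmax, protocol, dt = 0.05) {
  segs <- knobminer:::.protocolSegments(protocol)
  times <- seq(0, segs$t1[nrow(segs)], by = 1 / protocol@samplingRate)
  out <- numeric(length(times))
  R <- 0
  tNow <- 0
  ti <- 1L
  for (s in seq_len(nrow(segs))) {
    C <- segs$conc[s]
    f <- function(R) kon * C * (Rmax - R) - koff * R
    while (tNow < segs$t1[s] - 1e-9) {
      while (ti <= length(times) && times[ti] <= tNow + 1e-9) {
        out[ti] <- R
        ti <- ti + 1L
      }
      h <- min(dt, segs$t1[s] - tNow)
      k1 <- f(R); k2 <- f(R + h / 2 * k1); k3 <- f(R + h / 2 * k2)
      k4 <- f(R + h * k3)
      R <- R + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tNow <- tNow + h
    }
  }
  while (ti <= length(times)) { out[ti] <- R; ti <- ti + 1L }
  out
}

# -- misc -------------------------------------------------------------------

randomAa <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

randomNt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
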