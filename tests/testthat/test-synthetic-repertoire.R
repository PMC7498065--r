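# Synthetic repertoire generator: ground truth, determinism, SHM model.

test_that("degenerate configurations behave as contracted", {
  gs <- defaultGermlineSet()

  tr0 <- simulateRepertoire(gs, repertoireConfig(nClones = 50L,
                                                 ultralongFraction = 0,
                                                 seed = 2L))
  expect_equal(sum(tr0$is_ultralong), 0L)
  expect_true(all(is.na(tr0$knob_start)))

  trNoShm <- simulateRepertoire(gs, repertoireConfig(nClones = 60L,
                                                     shmRate = 0, seed = 3L))
  # every clone reconstructs exactly from its recorded germline segments
  vs <- as.character(vSegments(gs)); ds <- as.character(dSegments(gs))
  js <- as.character(jSegments(gs)); dup <- duplicationTail(gs)
  expected <- ifelse(trNoShm$is_ultralong,
                     paste0(vs[trNoShm$v_name], dup, dup,
                            ds[trNoShm$d_name], js[trNoShm$j_name]),
                     paste0(vs[trNoShm$v_name], ds[trNoShm$d_name],
                            js[trNoShm$j_name]))
  expect_identical(trNoShm$cdrh3_nt, unname(expected))
})

test_that("knob spans are planted iff ultralong, and truth is coherent", {
  tr <- simulateRepertoire(defaultGermlineSet(),
                           repertoireConfig(nClones = 80L, seed = 4L))
  expect_identical(is.na(tr$knob_start), !tr$is_ultralong)
  # translations match, and spans are non-empty within bounds
  for (i in seq_len(nrow(tr))) {
    expect_identical(translateThreeFrames(tr$cdrh3_nt[i])[["frame0"]],
                     tr$cdrh3_aa[i])
    if (tr$is_ultralong[i]) {
      expect_true(tr$knob_start[i] >= 1L)
      expect_true(tr$knob_end[i] > tr$knob_start[i])
      expect_true(tr$knob_end[i] <= nchar(tr$cdrh3_aa[i]))
    }
  }
  # ultralong clones exceed 90 nt, regular ones do not
  expect_true(all(nchar(tr$cdrh3_nt[tr$is_ultralong]) > 90L))
  expect_true(all(nchar(tr$cdrh3_nt[!tr$is_ultralong]) <= 90L))
})

test_that("observed ultralong fraction falls in the exact binomial 99% interval", {
  # qbinom bounds for p = 0.10, n = 2000 computed analytically
  n <- 2000L; p <- 0.10
  lo <- qbinom(0.005, n, p); hi <- qbinom(0.995, n, p)
  tr <- simulateRepertoire(defaultGermlineSet(),
                           repertoireConfig(nClones = n,
                                            ultralongFraction = p,
                                            seed = 1L))
  expect_gte(sum(tr$is_ultralong), lo)
  expect_lte(sum(tr$is_ultralong), hi)
})

test_that("identical seeds give bit-identical repertoires and FASTQ", {
  gs <- defaultGermlineSet()
  cfg <- repertoireConfig(nClones = 40L, seed = 9L)
  tr1 <- simulateRepertoire(gs, cfg)
  tr2 <- simulateRepertoire(gs, cfg)
  expect_identical(tr1, tr2)

  r1 <- emitReads(tr1, defaultBarcodes(), subRate = 0.01,
                  indelRate = 0.001, seed = 5L)
  r2 <- emitReads(tr1, defaultBarcodes(), subRate = 0.01,
                  indelRate = 0.001, seed = 5L)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writeFastq(r1, f1); writeFastq(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("noiseless reads embed the exact CDRH3 and honour depth", {
  tr <- simulateRepertoire(defaultGermlineSet(),
                           repertoireConfig(nClones = 25L, seed = 6L))
  reads <- emitReads(tr, defaultBarcodes(), subRate = 0, indelRate = 0)
  expect_equal(length(reads), sum(tr$copy_number))
  seqs <- as.character(reads)
  k <- 0L
  for (i in seq_len(nrow(tr))) {
    for (d in seq_len(tr$copy_number[i])) {
      k <- k + 1L
      expect_true(grepl(tr$cdrh3_nt[i], seqs[k], fixed = TRUE))
      # barcode sits right after the adaptor
      expect_identical(unname(substr(seqs[k], 31L, 38L)),
                       tr$sample_barcode[i])
    }
  }
})

test_that("error channel and input validation misbehave loudly", {
  tr <- simulateRepertoire(defaultGermlineSet(),
                           repertoireConfig(nClones = 5L, seed = 2L))
  expect_error(emitReads(tr, c("ACGTACGT", "ACGTACGT")), "collision|distinct")
  expect_error(emitReads(tr, c("ACGT")), "8 nt")
  expect_error(emitReads(tr, defaultBarcodes(), subRate = -0.1), ">= 0")
  expect_error(repertoireConfig(ultralongFraction = 1.2), "probability")
  expect_error(repertoireConfig(shmRate = -0.1), "probability")
  expect_error(GermlineSet(character(0), c(d = "TGT"), c(j = "AAA"),
                           "d", "ACGT"))
})

test_that("homopolymer indels are enriched relative to isolated bases", {
  # a read that is one long homopolymer vs one alternating sequence
  set.seed(11)
  homo <- strrep("A", 400L)
  alt <- strrep("ACGT", 100L)
  nIndel <- function(s) {
    out <- knobminer:::.injectErrors(s, 0, 0.01, 5)
    abs(nchar(out) - nchar(s))
  }
  dHomo <- mean(replicate(40, nIndel(homo)))
  dAlt <- mean(replicate(40, nIndel(alt)))
  expect_gt(dHomo, dAlt * 2)
})

test_that("cysteine parity of simulated knobs favours even counts", {
  tr <- simulateRepertoire(defaultGermlineSet(),
                           repertoireConfig(nClones = 10000L,
                                            ultralongFraction = 1,
                                            shmRate = 0.01, cysBias = 5,
                                            seed = 3L))
  knob <- substr(tr$cdrh3_aa, tr$knob_start + 1L, tr$knob_end)
  nC <- nchar(knob) - nchar(gsub("C", "", knob, fixed = TRUE))
  expect_gt(sum(nC %% 2L == 0L), sum(nC %% 2L == 1L))
})

test_that("germline sets round-trip through annotated FASTA", {
  gs <- defaultGermlineSet()
  tf <- tempfile(fileext = ".fasta")
  writeGermlineSet(gs, tf)
  gs2 <- readGermlineSet(tf)
  expect_identical(as.character(vSegments(gs)), as.character(vSegments(gs2)))
  expect_identical(as.character(dSegments(gs)), as.character(dSegments(gs2)))
  expect_identical(as.character(jSegments(gs)), as.character(jSegments(gs2)))
  expect_identical(ultralongCore(gs), ultralongCore(gs2))
  expect_identical(duplicationTail(gs), duplicationTail(gs2))
  unlink(tf)
  # the bundled file parses to the same set
  bundled <- readGermlineSet(system.file("extdata",
                                         "synthetic_germlines.fasta",
                                         package = "knobminer"))
  expect_identical(ultralongCoreAa(bundled), ultralongCoreAa(gs))
})
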