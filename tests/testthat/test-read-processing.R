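# Read processing: FASTQ/FASTA conversion, demultiplexing, three-frame
# translation, motif-anchored extraction, deduplication.

writeTempFastq <- function(lines) {
  tf <- tempfile(fileext = ".fastq")
  writeLines(lines, tf)
  tf
}

test_that("fastqToFasta preserves order and identifiers, drops qualities", {
  fq <- writeTempFastq(c("@r1 extra words", "ACGT", "+", "IIII",
                         "@r2", "GGCC", "+", "IIII",
                         "@r3", "TTAA", "+", "IIII"))
  fa <- tempfile(fileext = ".fasta")
  out <- fastqToFasta(fq, fa)
  expect_identical(names(out), c("r1", "r2", "r3"))
  expect_identical(as.character(out), c(r1 = "ACGT", r2 = "GGCC",
                                        r3 = "TTAA"))
  lines <- readLines(fa)
  expect_identical(lines[1:2], c(">r1", "ACGT"))

  # empty input -> empty output
  fqEmpty <- writeTempFastq(character(0))
  faEmpty <- tempfile(fileext = ".fasta")
  expect_length(fastqToFasta(fqEmpty, faEmpty), 0L)

  # malformed block names the record index
  bad <- writeTempFastq(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+"))
  expect_error(fastqToFasta(bad, tempfile()), "record 2|truncated record 2")
  unlink(c(fq, fa, fqEmpty, faEmpty, bad))
})

test_that("demultiplexing is an exact partition honouring maxMismatch", {
  bcs <- defaultBarcodes()
  mkRead <- function(bc) paste0(strrep("C", 30L), bc, randomNt(60L))
  set.seed(21)
  reads <- c(mkRead(bcs[1]), mkRead(bcs[2]),
             mkRead(paste0("T", substr(bcs[1], 2, 8))))  # 1 mismatch to bc1
  names(reads) <- paste0("r", 1:3)

  bins0 <- demultiplexReads(reads, bcs, maxMismatch = 0L,
                            adaptorLength = 30L)
  expect_equal(length(bins0[[bcs[1]]]), 1L)
  expect_equal(length(bins0[[bcs[2]]]), 1L)
  expect_equal(length(bins0$undetermined), 1L)

  bins1 <- demultiplexReads(reads, bcs, maxMismatch = 1L,
                            adaptorLength = 30L)
  expect_equal(length(bins1[[bcs[1]]]), 2L)
  expect_equal(length(bins1$undetermined), 0L)

  # partition property on a larger random batch
  reads100 <- vapply(sample(bcs, 100L, replace = TRUE), mkRead, character(1))
  bins <- demultiplexReads(reads100, bcs, maxMismatch = 1L,
                           adaptorLength = 30L)
  expect_equal(sum(vapply(bins, length, integer(1))), 100L)

  # barcode sheet too close for the mismatch budget
  expect_error(demultiplexReads(reads, c("AAAAAAAA", "AAAAAATT"),
                                maxMismatch = 1L),
               "ambiguous")
})

test_that("demultiplexing reproduces the generator's assignment exactly", {
  tr <- simulateRepertoire(defaultGermlineSet(),
                           repertoireConfig(nClones = 40L, seed = 12L))
  reads <- emitReads(tr, defaultBarcodes(), subRate = 0, indelRate = 0)
  bins <- demultiplexReads(reads, defaultBarcodes(), maxMismatch = 1L)
  perClone <- rep(tr$sample_barcode, tr$copy_number)
  for (b in defaultBarcodes())
    expect_equal(length(bins[[b]]), sum(perClone == b))
  expect_equal(length(bins$undetermined), 0L)
})

test_that("three-frame translation matches the codon table and an oracle", {
  expect_identical(translateThreeFrames("ATGGCC"),
                   c(frame0 = "MA", frame1 = "W", frame2 = "G"))
  expect_identical(translateThreeFrames("TAA")[["frame0"]], "*")
  # length contract on a random 300-mer
  set.seed(31)
  nt <- randomNt(300L)
  tr <- translateThreeFrames(nt)
  for (f in 0:2)
    expect_equal(nchar(tr[[f + 1L]]), (300L - f) %/% 3L)
  # oracle agreement on 1,000 random sequences, all frames
  set.seed(32)
  for (rep in seq_len(1000L)) {
    nt <- randomNt(sample(3:60, 1L))
    tr <- translateThreeFrames(nt)
    for (f in 0:2)
      expect_identical(tr[[f + 1L]], oracleTranslate(nt, f))
  }
})

test_that("CDRH3 extraction is anchored strictly between the primer motifs", {
  ex <- extractCdrh3("XXDSATYYGCGKLLVTVSSXX")
  expect_identical(ex$aa, "GCGK")
  expect_identical(ex$span, c(8L, 12L))
  # isoleucine variant of the downstream motif matches too
  expect_identical(extractCdrh3("XXDSATYYGCGKLLITVSSXX")$aa, "GCGK")
  # missing downstream anchor
  miss <- extractCdrh3("XXDSATYYGCGK")
  expect_true(isNone(miss))
  expect_identical(noneReason(miss), "no_downstream_motif")
  # downstream before upstream
  expect_identical(noneReason(extractCdrh3("LLVTVSSXXDSATYY")),
                   "downstream_before_upstream")
  # stop inside the span
  expect_identical(noneReason(extractCdrh3("DSATYYGC*GKLLVTVSS")),
                   "stop_in_cdrh3")
  # extraction is not idempotent: anchors are consumed
  expect_true(isNone(extractCdrh3(ex$aa)))
})

test_that("frame selection recovers the planted frame and filters stops", {
  tr <- simulateRepertoire(defaultGermlineSet(),
                           repertoireConfig(nClones = 20L, seed = 13L))
  reads <- emitReads(tr, defaultBarcodes(), subRate = 0, indelRate = 0)
  seqs <- as.character(reads)
  perClone <- rep(seq_len(nrow(tr)), tr$copy_number)
  for (k in seq_along(seqs)) {
    hit <- collectCdrh3(seqs[k])
    expect_false(isNone(hit))
    expect_identical(hit$cdrh3_nt, tr$cdrh3_nt[perClone[k]])
    expect_identical(hit$cdrh3_aa, tr$cdrh3_aa[perClone[k]])
    expect_equal(hit$frame, 1L)   # fixed library architecture phase
  }
  # a stop inside the only matching frame discards the read
  bad <- sub("GGTTATAGTTGTCCT", "GGTTAAAGTTGTCCT", seqs[1], fixed = TRUE)
  if (!identical(bad, seqs[1])) {
    res <- collectCdrh3(bad)
    expect_true(isNone(res))
  }
  expect_identical(noneReason(collectCdrh3("ACGTACGTACGT")), "no_frame")
})

test_that("deduplication counts copies and sorts deterministically", {
  df <- data.frame(sample_barcode = "ACGTACGT",
                   cdrh3_nt = c("TGTAAA", "TGTAAA", "TGTCCC"),
                   cdrh3_aa = c("CK", "CK", "CP"),
                   frame = 1L, stringsAsFactors = FALSE)
  out <- dedupeAndCount(df)
  expect_identical(out$cdrh3_nt, c("TGTAAA", "TGTCCC"))
  expect_identical(out$copy_number, c(2L, 1L))

  empty <- dedupeAndCount(df[0, ])
  expect_equal(nrow(empty), 0L)

  df$sample_barcode[3] <- "TGCATGCA"
  expect_error(dedupeAndCount(df), "single sample")
})

test_that("full processing recovers planted unique sequences and copies", {
  tr <- simulateRepertoire(defaultGermlineSet(),
                           repertoireConfig(nClones = 60L, seed = 14L))
  reads <- emitReads(tr, defaultBarcodes(), subRate = 0, indelRate = 0)
  proc <- processReads(reads, defaultBarcodes())
  # per-sample unique CDRH3 sets and summed copy numbers match the truth
  truthAgg <- aggregate(copy_number ~ sample_barcode + cdrh3_nt, tr, sum)
  got <- proc$cdr[order(proc$cdr$sample_barcode, proc$cdr$cdrh3_nt), ]
  truthAgg <- truthAgg[order(truthAgg$sample_barcode, truthAgg$cdrh3_nt), ]
  expect_identical(got$cdrh3_nt, truthAgg$cdrh3_nt)
  expect_identical(got$sample_barcode, truthAgg$sample_barcode)
  expect_equal(got$copy_number, truthAgg$copy_number)
})

test_that("theoretical diversity is the segment-count product", {
  expect_equal(theoreticalDiversity(1, 1, 1), 1)
  expect_equal(theoreticalDiversity(10, 10, 4), 400)
  expect_error(theoreticalDiversity(0, 10, 4), ">= 1")
  expect_error(theoreticalDiversity(10, -1, 4), ">= 1")
})
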