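# Knob/stalk boundaries, germline-cysteine mapping, fusion constructs
# and TEV digestion.

test_that("germline cysteines map through local alignment with SHM flags", {
  core <- ultralongCoreAa(defaultGermlineSet())
  corePos <- which(strsplit(core, "")[[1]] == "C") - 1L

  # exact embedding: positions shift by the prefix length, none mutated
  cdr <- paste0("CAKTTVHQ", core, "VAYVYIW")
  m <- mapGermlineCysteines(cdr, core)
  expect_equal(m$cdrh3_pos, corePos + 8L)
  expect_false(any(m$mutated))

  # one planted Cys->Tyr mutation keeps the position, flags it
  coreMut <- sub("C", "Y", core)   # first cysteine replaced
  cdrMut <- paste0("CAKTTVHQ", coreMut, "VAYVYIW")
  m2 <- mapGermlineCysteines(cdrMut, core)
  expect_equal(m2$cdrh3_pos, corePos + 8L)
  expect_identical(m2$mutated, c(TRUE, FALSE, FALSE, FALSE))

  # a sequence with nothing core-like fails the score floor
  expect_error(mapGermlineCysteines("KLKLKLKLKLKLKLKL", core), "core not found")
})

test_that("knob boundaries follow the first-Cys and descending-stalk rules", {
  kb <- callKnobBoundaries("TTVHQKTCPDGSCVAYVYIW", c(7L, 12L))
  expect_equal(knobSpan(kb), c(6L, 15L))
  expect_identical(knobSequence(kb), "TCPDGSCVA")
  expect_identical(kb@ascendingStalk, "TTVHQK")
  expect_identical(kb@descendingStalk, "YVYIW")

  # no aromatic residues after the last Cys: knob extends to the end
  expect_warning(kb2 <- callKnobBoundaries("TTKCPDGSCKGQG", c(3L, 8L)),
                 "knob extends")
  expect_equal(knobSpan(kb2), c(2L, 13L))
  expect_identical(kb2@descendingStalk, "")

  # a first germline cysteine at position 0 has no preceding residue
  expect_error(callKnobBoundaries("CPDGSC", c(0L, 5L)), "no preceding")
  expect_error(callKnobBoundaries("ACPDGSC", integer(0)), "empty")
})

test_that("simulated knob spans are recovered exactly on noiseless data", {
  tr <- simulateRepertoire(defaultGermlineSet(),
                           repertoireConfig(nClones = 100L,
                                            ultralongFraction = 1,
                                            shmRate = 0, seed = 16L))
  core <- ultralongCoreAa(defaultGermlineSet())
  hits <- 0L
  for (i in seq_len(nrow(tr))) {
    cys <- mapGermlineCysteines(tr$cdrh3_aa[i], core)
    kb <- callKnobBoundaries(tr$cdrh3_aa[i], cys$cdrh3_pos)
    if (identical(knobSpan(kb), c(tr$knob_start[i], tr$knob_end[i])))
      hits <- hits + 1L
  }
  expect_gte(hits / nrow(tr), 0.99)
})

test_that("stalk/knob/stalk always reconstructs the CDRH3 exactly", {
  tr <- simulateRepertoire(defaultGermlineSet(),
                           repertoireConfig(nClones = 40L,
                                            ultralongFraction = 1,
                                            seed = 17L))
  core <- ultralongCoreAa(defaultGermlineSet())
  for (i in seq_len(nrow(tr))) {
    cys <- suppressWarnings(mapGermlineCysteines(tr$cdrh3_aa[i], core))
    kb <- suppressWarnings(callKnobBoundaries(tr$cdrh3_aa[i], cys$cdrh3_pos))
    expect_identical(paste0(kb@ascendingStalk, knobSequence(kb),
                            kb@descendingStalk),
                     tr$cdrh3_aa[i])
  }
})

test_that("CDRH3-ScFc construction concatenates leader, insert, template", {
  tmpl <- defaultScFcTemplate()
  fc <- buildCdrh3ScFc("ACDC", tmpl)
  leader <- "MEWSWVFLFFLSVTTGVHS"
  expect_identical(orfSequence(fc), paste0(leader, "ACDC", tmpl))
  expect_equal(nchar(orfSequence(fc)),
               nchar(leader) + 4L + nchar(tmpl))
  expect_equal(insertSpan(fc), c(nchar(leader), nchar(leader) + 4L))
  expect_equal(length(tevSites(fc)), 1L)

  expect_error(buildCdrh3ScFc("", tmpl), "non-empty")
  expect_error(buildCdrh3ScFc("ACDC", "NOMOTIFHHHHHHHHHH"), "TEV")
  expect_error(buildCdrh3ScFc("ACDC", "AAENLYFQGAA"), "poly-His")
})

test_that("Fab-knob grafts carry exactly two flanking TEV sites", {
  fc <- buildFabKnobFusion("KCK", "AAAA", 2L)
  expect_identical(orfSequence(fc), "AAENLYFQGKCKENLYFQGAA")
  expect_equal(tevSites(fc), c(2L, 12L))
  expect_identical(substr(orfSequence(fc), insertSpan(fc)[1L] + 1L,
                          insertSpan(fc)[2L]), "KCK")
  expect_error(buildFabKnobFusion("KCK", "AAAA", 7L), "outside")
  expect_error(buildFabKnobFusion("", "AAAA", 2L), "non-empty")
})

test_that("TEV digestion cleaves after ENLYFQ|(G/S) and conserves length", {
  d <- tevDigest("AAENLYFQGBB")
  expect_identical(d$fragment, c("AAENLYFQ", "GBB"))

  none <- tevDigest("PEPTIDEWITHOUTSITE")
  expect_equal(nrow(none), 1L)
  expect_identical(none$fragment, "PEPTIDEWITHOUTSITE")

  # ENLYFQ followed by something else is not cleaved
  expect_equal(nrow(tevDigest("AAENLYFQABB")), 1L)

  # doubly flanked graft: 3 fragments, middle contains the knob with
  # explicit remnant bookkeeping
  fc <- buildFabKnobFusion("KCWCK", defaultFabAcceptor()$heavy,
                           defaultFabAcceptor()$insertion_point)
  d3 <- tevDigest(orfSequence(fc))
  expect_equal(nrow(d3), 3L)
  expect_true(grepl("KCWCK", d3$fragment[2L], fixed = TRUE))
  expect_identical(d3$n_term_remnant[2L], "G")
  expect_true(d3$c_term_motif[2L])
  # fragments concatenate to the ORF
  expect_identical(paste(d3$fragment, collapse = ""), orfSequence(fc))
  expect_equal(sum(nchar(d3$fragment)), nchar(orfSequence(fc)))
})
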