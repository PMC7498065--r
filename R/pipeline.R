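# End-to-end pipeline driver and machine-readable reporting.

#' Assemble and validate a pipeline configuration
#'
#' Inputs are either a FASTQ path (`readsPath`) or a simulation request
#' (`simulate = TRUE`, using `germlines` + `repertoire`); thresholds
#' mirror the stage functions. The configuration round-trips through JSON
#' losslessly and its semantic content is hashed into the run manifest.
#'
#' @param readsPath Optional path to an existing FASTQ file.
#' @param simulate Generate reads from the synthetic repertoire instead?
#' @param germlines A [GermlineSet] (simulation and knob annotation).
#' @param repertoire A [RepertoireConfig] (simulation only).
#' @param barcodes Sample barcodes.
#' @param subRate,indelRate,readSeed Read-emission error channel.
#' @param maxMismatch,minCopies Extraction thresholds.
#' @param lengthThresholdNt,requireDuplication Ultralong classification.
#' @param identityPct,identityMode,knobOnly Clonotyping thresholds;
#'   `knobOnly` clusters knob sequences instead of full CDRH3.
#' @param charges Charge states for mass prediction.
#' @param outputDir Optional directory for TSV/FASTA/JSON outputs.
#' @return A validated `list` of class `pipelineConfig`.
#' @export
pipelineConfig <- function(readsPath = NULL, simulate = is.null(readsPath),
                           germlines = defaultGermlineSet(),
                           repertoire = repertoireConfig(),
                           barcodes = defaultBarcodes(),
                           subRate = 0, indelRate = 0, readSeed = 1L,
                           maxMismatch = 1L, minCopies = 1L,
                           lengthThresholdNt = 90L,
                           requireDuplication = FALSE,
                           identityPct = 75, identityMode = "geq",
                           knobOnly = FALSE, charges = 4L,
                           outputDir = NULL) {
  if (!simulate && (is.null(readsPath) || !file.exists(readsPath)))
    stop("readsPath does not exist and simulate = FALSE")
  if (identityPct <= 0 || identityPct > 100)
    stop("identityPct must lie in (0, 100]")
  if (lengthThresholdNt < 1L) stop("lengthThresholdNt must be >= 1")
  validObject(germlines)
  validObject(repertoire)
  structure(list(
    readsPath = readsPath, simulate = simulate, germlines = germlines,
    repertoire = repertoire, barcodes = barcodes, subRate = subRate,
    indelRate = indelRate, readSeed = as.integer(readSeed),
    maxMismatch = as.integer(maxMismatch), minCopies = as.integer(minCopies),
    lengthThresholdNt = as.integer(lengthThresholdNt),
    requireDuplication = requireDuplication,
    identityPct = identityPct, identityMode = identityMode,
    knobOnly = knobOnly, charges = as.integer(charges),
    outputDir = outputDir), class = "pipelineConfig")
}

# semantic content of a config, for hashing (paths and objects rendered
# to stable primitives; outputDir excluded as non-semantic)
#' @noRd
.configSemantics <- function(config) {
  list(
    readsPath = config$readsPath, simulate = config$simulate,
    germlines = list(
      v = as.character(vSegments(config$germlines)),
      d = as.character(dSegments(config$germlines)),
      j = as.character(jSegments(config$germlines)),
      core = config$germlines@ighd82Name,
      tail = duplicationTail(config$germlines)),
    repertoire = list(
      nClones = config$repertoire@nClones,
      ultralongFraction = config$repertoire@ultralongFraction,
      shmRate = config$repertoire@shmRate,
      cysBias = config$repertoire@cysBias,
      cloneSizeProb = config$repertoire@cloneSizeProb,
      seed = config$repertoire@seed),
    barcodes = config$barcodes, subRate = config$subRate,
    indelRate = config$indelRate, readSeed = config$readSeed,
    maxMismatch = config$maxMismatch, minCopies = config$minCopies,
    lengthThresholdNt = config$lengthThresholdNt,
    requireDuplication = config$requireDuplication,
    identityPct = config$identityPct, identityMode = config$identityMode,
    knobOnly = config$knobOnly, charges = config$charges)
}

#' Run the full knob-domain discovery pipeline
#'
#' Stages, in order: extract (reads to unique CDRH3 table), classify
#' (ultralong annotation), clonotype, knob-annotate, design (CDRH3-ScFc
#' and Fab-knob constructs), mass (disulphide-corrected predictions).
#' The run is deterministic given the configured seeds.
#'
#' @param config A [pipelineConfig()].
#' @return `list(manifest =, truth =, cdr =, ann =, clusters =, knobs =,
#'   constructs =, masses =)`. The manifest records the package version,
#'   a hash of the semantic configuration, per-stage record counts and
#'   any output paths; when `outputDir` is set, tables, construct FASTA
#'   and the manifest JSON are written there.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  truth <- NULL
  if (config$simulate) {
    truth <- simulateRepertoire(config$germlines, config$repertoire,
                                config$barcodes)
    reads <- emitReads(truth, config$barcodes, config$subRate,
                       config$indelRate, config$readSeed)
  } else {
    reads <- readFastq(config$readsPath)
  }

  proc <- processReads(reads, config$barcodes, config$maxMismatch,
                       config$minCopies)
  cdr <- proc$cdr

  ann <- annotateUltralong(cdr, config$lengthThresholdNt,
                           config$requireDuplication,
                           duplicationTail(config$germlines))
  ul <- ann[ann$is_ultralong, , drop = FALSE]

  knobs <- list()
  knobRows <- list()
  coreAa <- ultralongCoreAa(config$germlines)
  for (i in seq_len(nrow(ul))) {
    kn <- tryCatch({
      cys <- mapGermlineCysteines(ul$cdrh3_aa[i], coreAa)
      suppressWarnings(callKnobBoundaries(ul$cdrh3_aa[i], cys$cdrh3_pos))
    }, error = function(e) NULL)
    if (!is.null(kn)) {
      knobs[[length(knobs) + 1L]] <- kn
      knobRows[[length(knobRows) + 1L]] <- data.frame(
        cdrh3_aa = ul$cdrh3_aa[i], knob_aa = knobSequence(kn),
        knob_start = knobSpan(kn)[1L], knob_end = knobSpan(kn)[2L],
        sample_barcode = ul$sample_barcode[i],
        copy_number = ul$copy_number[i], stringsAsFactors = FALSE)
    }
  }
  knobTab <- if (length(knobRows)) do.call(rbind, knobRows) else
    data.frame(cdrh3_aa = character(0), knob_aa = character(0),
               knob_start = integer(0), knob_end = integer(0),
               sample_barcode = character(0), copy_number = integer(0))

  clSeqs <- if (config$knobOnly) unique(knobTab$knob_aa) else
    unique(ul$cdrh3_aa)
  clCopy <- if (config$knobOnly)
    vapply(clSeqs, function(s)
      sum(knobTab$copy_number[knobTab$knob_aa == s]), numeric(1)) else
    vapply(clSeqs, function(s)
      sum(ul$copy_number[ul$cdrh3_aa == s]), numeric(1))
  clusters <- clusterClonotypes(clSeqs, config$identityPct,
                                config$identityMode, clCopy)

  constructs <- list()
  acceptor <- defaultFabAcceptor()
  for (i in seq_len(nrow(knobTab))) {
    constructs[[length(constructs) + 1L]] <-
      buildCdrh3ScFc(knobTab$cdrh3_aa[i])
    constructs[[length(constructs) + 1L]] <-
      buildFabKnobFusion(knobTab$knob_aa[i], acceptor$heavy,
                         acceptor$insertion_point)
  }

  masses <- lapply(seq_len(nrow(knobTab)), function(i)
    massPrediction(knobTab$knob_aa[i], charges = config$charges))

  counts <- c(
    reads = length(reads),
    unique_cdrh3 = nrow(cdr),
    annotated = nrow(ann),
    ultralong = nrow(ul),
    knob_annotated = nrow(knobTab),
    clonotyped_sequences = length(clSeqs),
    constructs = length(constructs),
    mass_predictions = length(masses))

  outputs <- character(0)
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    outputs <- .writePipelineOutputs(config$outputDir, ann, clusters,
                                     knobTab, constructs, masses)
  }

  manifest <- list(
    package = "knobminer",
    version = as.character(utils::packageVersion("knobminer")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = .jsonHash(.configSemantics(config)),
    counts = as.list(counts),
    discards = as.list(proc$discards),
    outputs = outputs)
  if (!is.null(config$outputDir)) {
    manifestPath <- file.path(config$outputDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA)
    manifest$outputs <- c(manifest$outputs, manifestPath)
  }

  list(manifest = manifest, truth = truth, cdr = cdr, ann = ann,
       clusters = clusters, knobs = knobTab, constructs = constructs,
       masses = masses)
}

#' @noRd
.writePipelineOutputs <- function(dir, ann, clusters, knobTab, constructs,
                                  masses) {
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths, w(ann, "cdrh3_annotated.tsv"))
  paths <- c(paths, w(clusters, "clonotypes.tsv"))
  paths <- c(paths, w(knobTab, "knob_annotations.tsv"))
  if (length(constructs)) {
    orfs <- Biostrings::AAStringSet(vapply(constructs, orfSequence,
                                           character(1)))
    names(orfs) <- vapply(seq_along(constructs), function(i)
      sprintf("construct%03d type=%s insert=%d-%d", i,
              constructs[[i]]@constructType,
              insertSpan(constructs[[i]])[1L],
              insertSpan(constructs[[i]])[2L]), character(1))
    p <- file.path(dir, "constructs.fasta")
    Biostrings::writeXStringSet(orfs, p)
    paths <- c(paths, p)
  }
  if (length(masses)) {
    massTab <- do.call(rbind, lapply(masses, function(m) data.frame(
      peptide = m@peptideAa, n_disulphides = m@nDisulphides,
      mono_mass = m@monoisotopicMass, avg_mass = m@averageMass,
      stringsAsFactors = FALSE)))
    paths <- c(paths, w(massTab, "mass_predictions.tsv"))
  }
  paths
}

#' Machine-readable cohort summary
#'
#' Summarises the annotated cohort and its clonotype structure: unique
#' CDRH3 count, ultralong count and percentage (one decimal), clonotype
#' and singleton counts, and a cysteine parity table.
#'
#' @param ann Annotated CDRH3 table (from [annotateUltralong()]).
#' @param clusters Clonotype table (from [clusterClonotypes()]); optional.
#' @return `list(n_total_unique, n_ultralong, ultralong_pct,
#'   n_clonotypes, n_singletons, cys_parity)`; `ultralong_pct` is `NA`
#'   when the cohort is empty.
#' @export
summaryReport <- function(ann, clusters = NULL) {
  nTotal <- nrow(ann)
  nUl <- sum(ann$is_ultralong)
  cs <- if (nTotal) clonotypeSummary(clusters %||%
                                     data.frame(clonotype_id = character(0),
                                                size = integer(0))) else
    list(n_clonotypes = 0L, n_singletons = 0L)
  parity <- if (nTotal) as.list(table(ann$cys_parity[ann$is_ultralong])) else
    list()
  list(n_total_unique = nTotal,
       n_ultralong = nUl,
       ultralong_pct = pctUltralong(nUl, nTotal),
       n_clonotypes = cs$n_clonotypes,
       n_singletons = cs$n_singletons,
       cys_parity = parity)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
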