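# ---- end-to-end pipeline orchestration -------------------------------------

writeManifest <- function(path, stage, config, inputs, counts, seed) {
  manifest <- list(
    tool = "panelCNV",
    version = as.character(packageVersion("panelCNV")),
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = lapply(setNames(nm = names(.configKeys)),
                    function(k) slot(config, .configKeys[[k]])),
    inputs = lapply(inputs, function(f)
      if (!is.na(f) && file.exists(f))
        list(path = f, md5 = unname(tools::md5sum(f))) else list(path = f)),
    counts = counts)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)  # atomic publish
  invisible(path)
}

#' Simulate a fixture bundle (pipeline stage)
#'
#' @param out output directory for the bundle.
#' @param spec a \linkS4class{SimSpec} or path to a YAML file of
#'   \code{\link{simSpec}} arguments (implants given as a list of row
#'   lists).
#' @param seed optional integer overriding the spec seed.
#' @return Named vector of bundle paths, invisibly.
#' @export
runSimulate <- function(out, spec = simSpec(), seed = NULL) {
  if (is.character(spec)) spec <- readSimSpec(spec)
  if (!is.null(seed)) spec@seed <- as.integer(seed)
  paths <- writeFixtureBundle(spec, out,
                              config = panelConfig(rngSeed = spec@seed))
  writeManifest(file.path(out, "manifest.json"), "simulate",
                panelConfig(rngSeed = spec@seed), as.list(paths),
                list(samples = spec@nSamples,
                     probes = spec@nGenes * spec@probesPerGene,
                     implants = nrow(spec@implants)),
                spec@seed)
  invisible(paths)
}

readSimSpec <- function(path) {
  if (!file.exists(path)) ioError("simulation spec not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$implants))
    raw$implants <- do.call(rbind, lapply(raw$implants, as.data.frame))
  do.call(simSpec, raw)
}

#' Extract probe-level depth from alignments (pipeline stage)
#'
#' @param probeFile probe design TSV.
#' @param sampleSheet sample sheet TSV; its \code{bam} column locates the
#'   alignment files.
#' @param out output prefix; writes \code{<out>.depth.tsv} and a manifest.
#' @param mode "hyb" or "pcr".
#' @param config a \linkS4class{PanelConfig}.
#' @return Path of the depth TSV, invisibly.
#' @export
runDepth <- function(probeFile, sampleSheet, out, mode = c("hyb", "pcr"),
                     config = panelConfig()) {
  mode <- match.arg(mode)
  probes <- parseProbeFile(probeFile)
  samples <- parseSampleSheet(sampleSheet)
  if (anyNA(samples$bam))
    validationError("sample sheet must provide a 'bam' column for runDepth")
  bams <- setNames(samples$bam, samples$sample_id)
  pd <- if (mode == "pcr") depthPcr(bams, probes, config, samples)
        else depthHyb(bams, probes, config, samples)
  if (all(depthValues(pd) == 0))
    warning("all probe depths are zero; check the alignment inputs")
  depthPath <- paste0(out, ".depth.tsv")
  writeDepthMatrix(pd, depthPath)
  writeManifest(paste0(out, ".manifest.json"), "depth", config,
                list(probes = probeFile, samples = sampleSheet),
                list(samples = ncol(pd), probes = nrow(pd)),
                config@rngSeed)
  invisible(depthPath)
}

#' Run the full calling pipeline (pipeline stage)
#'
#' Loads a depth matrix (or extracts it from BAMs when \code{depthFile} is
#' NULL and the sample sheet has a \code{bam} column), applies chromosome X
#' normalization, sample QC, bootstrap regression, segmentation with the
#' rescue rule, confidence scoring, and (optionally) plotting.  Writes the
#' QC report, model summary, ratio table, candidate TSV/BED and a run
#' manifest into \code{out}.
#'
#' @param probeFile probe design TSV (ignored when \code{depthFile} carries
#'   the probe columns, as bundle depth files do).
#' @param sampleSheet sample sheet TSV.
#' @param out output directory.
#' @param depthFile precomputed depth matrix TSV (the bundle contract), or
#'   NULL to extract from BAMs.
#' @param mode "hyb" or "pcr".
#' @param config a \linkS4class{PanelConfig} or path to a YAML config.
#' @param plots generate plots (default TRUE).
#' @return The scored candidate data.frame, invisibly.
#' @export
runCall <- function(probeFile = NULL, sampleSheet, out, depthFile = NULL,
                    mode = c("hyb", "pcr"), config = panelConfig(),
                    plots = TRUE) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- loadConfig(config)
  samples <- parseSampleSheet(sampleSheet)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (is.null(depthFile)) {
    if (is.null(probeFile))
      validationError("either depthFile or probeFile+BAMs must be given")
    depthFile <- runDepth(probeFile, sampleSheet, file.path(out, "depth"),
                          mode, config)
  }
  pd <- readDepthMatrix(depthFile, samples = samples,
                        mode = if (mode == "hyb") "hybridization" else "pcr")
  pd <- normalizeX(pd)

  qc <- filterSamples(sampleCorrelations(pd), config, mode = captureMode(pd))
  writeQcReport(qc$reports, file.path(out, "sample_qc.tsv"))
  pdPass <- pd[, qc$pass]

  fit <- fitProbeModels(pdPass, config)
  writeModelSummary(fit, file.path(out, "probe_models.tsv"))
  writeRatioTable(fit, file.path(out, "probe_ratios.tsv"))

  candidates <- callCnvs(fit, config)
  writeCandidates(candidates, file.path(out, "cnv_candidates.tsv"))
  candidatesToBed(candidates, file.path(out, "cnv_candidates.bed"))

  if (plots)
    savePanelPlots(fit, candidates, file.path(out, "plots"),
                   formats = "pdf")

  message(sprintf("score histogram: %s",
    paste(sprintf("%d:%d", 0:5,
                  tabulate(factor(candidates$score, 0:5), nbins = 6L)),
          collapse = " ")))
  writeManifest(file.path(out, "manifest.json"), "call", config,
                list(depth = depthFile, samples = sampleSheet),
                list(samples_in = ncol(pd),
                     samples_pass = length(qc$pass),
                     probes = nrow(pd),
                     candidates = nrow(candidates),
                     score5 = sum(candidates$score == 5)),
                config@rngSeed)
  invisible(candidates)
}

#' Re-score an existing candidate table (pipeline stage)
#'
#' Re-evaluates the five confidence criteria under new thresholds without
#' refitting models.
#'
#' @param candidateFile candidate TSV produced by \code{\link{runCall}}.
#' @param out output TSV path.
#' @param config a \linkS4class{PanelConfig} or YAML path.
#' @return The rescored data.frame, invisibly.
#' @export
runScore <- function(candidateFile, out, config = panelConfig()) {
  if (is.character(config)) config <- loadConfig(config)
  if (!file.exists(candidateFile))
    ioError("candidate table not found: %s", candidateFile)
  df <- read.delim(candidateFile, stringsAsFactors = FALSE)
  df <- scoreCandidates(df, config)
  write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Map a pipeline condition to a shell exit code
#'
#' Used by the command-line wrapper: validation errors exit 2, QC refusals
#' 3, I/O errors 4, anything else 1.
#'
#' @param cond a condition object.
#' @return Integer exit code.
#' @export
pcnvExitCode <- function(cond) {
  if (inherits(cond, "pcnv_validation_error")) 2L
  else if (inherits(cond, "pcnv_qc_error")) 3L
  else if (inherits(cond, "pcnv_io_error")) 4L
  else 1L
}
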