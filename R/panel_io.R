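#' Construct a pipeline configuration
#'
#' Returns a \linkS4class{PanelConfig} filled with the published defaults;
#' any argument overrides the corresponding default.  Thresholds that are
#' log2 quantities (\code{log2DelMax}, \code{log2DupMin}) are given on the
#' log2 scale.
#'
#' @param nBootstrap number of bootstrap regressions per probe (default 1000).
#' @param thDel,thDup deletion/duplication ratio thresholds (0.7 / 1.3).
#' @param probCutoff evidence fraction for a probe-level call (0.5).
#' @param profileCap cap on ratios entering segmentation profiles (16).
#' @param r2ProbeMin minimum mean bootstrap R-squared per probe (0.8).
#' @param corrMin sample QC top-quadrant correlation cutoff (0.7).
#' @param mqvMin minimum read mapping quality (0).
#' @param minSamples minimum QC-passing cohort size (6).
#' @param probeCntMin,log2DelMax,log2DupMin,stdMax,ciMax,r2ScoreMin the five
#'   confidence-score thresholds (2, log2(0.6), log2(1.4), 0.4, 0.4, 0.85).
#' @param cbsAlpha,cbsPerms segmentation permutation test: significance
#'   level (0.01) and number of permutations (1000).
#' @param rescueProb evidence fraction defining a "strong" probe signal for
#'   the consecutive-run rescue rule (0.5, i.e. the probe-call cutoff).
#' @param rngSeed integer seed for all stochastic steps.
#' @return A validated \linkS4class{PanelConfig}.
#' @examples
#' cfg <- panelConfig()
#' cfg@thDel
#' @export
panelConfig <- function(nBootstrap = 1000L, thDel = 0.7, thDup = 1.3,
                        probCutoff = 0.5, profileCap = 16,
                        r2ProbeMin = 0.8, corrMin = 0.7, mqvMin = 0L,
                        minSamples = 6L, probeCntMin = 2L,
                        log2DelMax = log2(0.6), log2DupMin = log2(1.4),
                        stdMax = 0.4, ciMax = 0.4, r2ScoreMin = 0.85,
                        cbsAlpha = 0.01, cbsPerms = 1000L, rescueProb = 0.5,
                        rngSeed = 20260101L) {
  if (thDel >= thDup)
    validationError("thDel (%.3g) must be below thDup (%.3g)", thDel, thDup)
  new("PanelConfig",
      nBootstrap = as.integer(nBootstrap), thDel = thDel, thDup = thDup,
      probCutoff = probCutoff, profileCap = profileCap,
      r2ProbeMin = r2ProbeMin, corrMin = corrMin,
      mqvMin = as.integer(mqvMin), minSamples = as.integer(minSamples),
      probeCntMin = as.integer(probeCntMin),
      log2DelMax = log2DelMax, log2DupMin = log2DupMin,
      stdMax = stdMax, ciMax = ciMax, r2ScoreMin = r2ScoreMin,
      cbsAlpha = cbsAlpha, cbsPerms = as.integer(cbsPerms),
      rescueProb = rescueProb, rngSeed = as.integer(rngSeed))
}

# keys accepted in the YAML configuration, mapped to constructor arguments
.configKeys <- c(
  n_bootstrap = "nBootstrap", th_del = "thDel", th_dup = "thDup",
  prob_cutoff = "probCutoff", profile_cap = "profileCap",
  r2_probe_min = "r2ProbeMin", corr_min = "corrMin", mqv_min = "mqvMin",
  min_samples = "minSamples", probe_cnt_min = "probeCntMin",
  log2_del_max = "log2DelMax", log2_dup_min = "log2DupMin",
  std_max = "stdMax", ci_max = "ciMax", r2_score_min = "r2ScoreMin",
  cbs_alpha = "cbsAlpha", cbs_perms = "cbsPerms", rescue_prob = "rescueProb",
  rng_seed = "rngSeed"
)

#' Load a configuration from a YAML file
#'
#' A missing or NULL \code{path} yields all defaults; a partial file
#' overrides only the keys it names (flat key: value pairs, snake_case as in
#' \code{n_bootstrap}, \code{th_del}, ...).
#'
#' @param path path to a YAML file, or NULL for pure defaults.
#' @param ... further overrides passed to \code{\link{panelConfig}}; they
#'   take precedence over the file.
#' @return A \linkS4class{PanelConfig}.
#' @export
loadConfig <- function(path = NULL, ...) {
  args <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) ioError("config file not found: %s", path)
    raw <- yaml::read_yaml(path)
    unknown <- setdiff(names(raw), names(.configKeys))
    if (length(unknown))
      validationError("unknown config keys: %s", paste(unknown, collapse = ", "))
    args <- setNames(raw, .configKeys[names(raw)])
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(panelConfig, args)
}

#' Write a configuration as YAML
#'
#' @param config a \linkS4class{PanelConfig}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeConfig <- function(config, path) {
  vals <- lapply(.configKeys, function(s) {
    v <- slot(config, s)
    if (is.integer(v)) as.integer(v) else as.numeric(v)
  })
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Parse a probe/amplicon design file
#'
#' Reads the tab-delimited panel design (header row; columns \code{chrom},
#' \code{start}, \code{end}, \code{gene}, optional \code{transcript},
#' \code{exon}, \code{pool}, \code{probe_id}).  Coordinates are interpreted
#' as BED-like 0-based half-open intervals and converted to the 1-based
#' \link[GenomicRanges]{GRanges} representation used internally.  Probes are
#' returned sorted by (chrom, start, end); a missing pool column assigns
#' every probe to a single default pool with a warning; duplicated
#' (chrom, start, end, pool) rows are rejected.
#'
#' @param path path to the TSV design file.
#' @return A \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{probe_id}, \code{gene}, \code{transcript}, \code{exon},
#'   \code{pool}.
#' @export
parseProbeFile <- function(path) {
  if (!file.exists(path)) ioError("probe file not found: %s", path)
  df <- tryCatch(
    read.delim(path, header = TRUE, stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) ioError("cannot read probe file %s: %s",
                                path, conditionMessage(e)))
  if (nrow(df) == 0L) validationError("probe file %s has no data rows", path)
  need <- c("chrom", "start", "end", "gene")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    validationError("probe file lacks required columns: %s",
                    paste(miss, collapse = ", "))
  if (!"pool" %in% colnames(df)) {
    warning("probe file has no 'pool' column; assigning all probes to 'pool1'")
    df$pool <- "pool1"
  }
  if (!"transcript" %in% colnames(df)) df$transcript <- NA_character_
  if (!"exon" %in% colnames(df)) df$exon <- NA_character_

  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    validationError("malformed probe row at line %d of %s",
                    bad[1] + 1L, path)  # +1 for the header line
  if (any(start >= end))
    validationError("probe with start >= end at line %d of %s",
                    which(start >= end)[1] + 1L, path)
  key <- paste(df$chrom, start, end, df$pool)
  if (anyDuplicated(key))
    validationError("duplicate probe (chrom,start,end,pool) at line %d of %s",
                    which(duplicated(key))[1] + 1L, path)

  probeIds <- if ("probe_id" %in% colnames(df)) df$probe_id else
    paste0(df$chrom, ":", start, "-", end, ":", df$pool)
  if (anyDuplicated(probeIds))
    validationError("probe_id values are not unique in %s", path)

  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    probe_id = probeIds, gene = df$gene,
    transcript = df$transcript, exon = df$exon, pool = df$pool)
  gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr),
                            ignore.strand = TRUE)
  names(gr) <- S4Vectors::mcols(gr)$probe_id
  gr
}

#' Write a probe collection back to the TSV design dialect
#'
#' Inverse of \code{\link{parseProbeFile}} (coordinates are emitted 0-based
#' half-open), so that parse -> write -> parse round-trips.
#'
#' @param probes a probe \link[GenomicRanges]{GRanges}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeProbeFile <- function(probes, path) {
  mc <- S4Vectors::mcols(probes)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(probes)),
    start = GenomicRanges::start(probes) - 1L,
    end = GenomicRanges::end(probes),
    gene = mc$gene, transcript = mc$transcript, exon = mc$exon,
    pool = mc$pool, probe_id = mc$probe_id,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a sample sheet
#'
#' Tab-delimited with header; columns \code{sample_id}, \code{gender} and
#' optionally \code{bam}.  Gender tokens \code{male}/\code{m} and
#' \code{female}/\code{f} are accepted case-insensitively; anything else is
#' an error, as is a duplicated sample id.
#'
#' @param path path to the TSV sample sheet.
#' @return A data.frame with columns \code{sample_id}, \code{gender},
#'   \code{bam}.
#' @export
parseSampleSheet <- function(path) {
  if (!file.exists(path)) ioError("sample sheet not found: %s", path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("sample_id", "gender") %in% colnames(df)))
    validationError("sample sheet needs 'sample_id' and 'gender' columns")
  if (anyDuplicated(df$sample_id))
    validationError("duplicate sample_id '%s' in sample sheet",
                    df$sample_id[duplicated(df$sample_id)][1])
  df$gender <- normalizeGender(df$gender)
  if (!"bam" %in% colnames(df)) df$bam <- NA_character_
  df[, c("sample_id", "gender", "bam")]
}

normalizeGender <- function(g) {
  tok <- tolower(trimws(as.character(g)))
  out <- ifelse(tok %in% c("male", "m"), "male",
         ifelse(tok %in% c("female", "f"), "female", NA_character_))
  if (anyNA(out) && any(!is.na(tok) & is.na(out)))
    validationError("unknown gender token '%s'", tok[is.na(out)][1])
  out
}

#' Assemble a PanelDepth container
#'
#' @param depth numeric probe-by-sample matrix of read depths.
#' @param probes probe \link[GenomicRanges]{GRanges} as returned by
#'   \code{\link{parseProbeFile}} (same order and length as rows of
#'   \code{depth}).
#' @param samples data.frame as returned by \code{\link{parseSampleSheet}},
#'   or NULL to take sample ids from \code{colnames(depth)}.
#' @param mode "hybridization" or "pcr".
#' @param xNormalized whether female chromosome X depths are already halved.
#' @return A \linkS4class{PanelDepth}.
#' @export
PanelDepth <- function(depth, probes, samples = NULL,
                       mode = c("hybridization", "pcr"),
                       xNormalized = FALSE) {
  mode <- match.arg(mode)
  depth <- as.matrix(depth)
  if (nrow(depth) != length(probes))
    validationError("depth has %d rows but panel has %d probes",
                    nrow(depth), length(probes))
  if (is.null(samples)) {
    if (is.null(colnames(depth)))
      validationError("either a sample sheet or depth column names required")
    samples <- data.frame(sample_id = colnames(depth),
                          gender = NA_character_, bam = NA_character_,
                          stringsAsFactors = FALSE)
  }
  if (!is.null(colnames(depth))) {
    miss <- setdiff(samples$sample_id, colnames(depth))
    if (length(miss))
      validationError("samples absent from depth matrix: %s",
                      paste(miss, collapse = ", "))
    depth <- depth[, samples$sample_id, drop = FALSE]
  } else colnames(depth) <- samples$sample_id
  rownames(depth) <- S4Vectors::mcols(probes)$probe_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(depth = depth), rowRanges = probes,
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
  new("PanelDepth", se, captureMode = mode, xNormalized = xNormalized)
}

#' @describeIn PanelDepth the depth assay matrix.
#' @param x,object a \linkS4class{PanelDepth}.
#' @export
depthValues <- function(x) SummarizedExperiment::assay(x, "depth")

#' @describeIn PanelDepth the capture mode ("hybridization" or "pcr").
#' @export
captureMode <- function(x) x@captureMode

#' @describeIn PanelDepth whether chromosome X normalization was applied.
#' @export
isXNormalized <- function(x) x@xNormalized

#' @describeIn PanelDepth pool label of every probe.
#' @export
probePools <- function(x)
  as.character(S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$pool)

setMethod("show", "PanelDepth", function(object) {
  cat(sprintf("PanelDepth: %d probes x %d samples (%s capture)\n",
              nrow(object), ncol(object), object@captureMode))
  cat(sprintf("  pools: %s | chrX normalized: %s\n",
              paste(unique(probePools(object)), collapse = ", "),
              object@xNormalized))
})

setMethod("show", "PanelConfig", function(object) {
  cat("PanelConfig:\n")
  for (s in slotNames(object))
    cat(sprintf("  %-12s %s\n", s, format(slot(object, s), digits = 4)))
})

setMethod("show", "CnvFit", function(object) {
  q <- table(factor(object@quality, c("ok", "faulty_probe", "low_r2")))
  cat(sprintf("CnvFit: %d probes x %d samples, %d bootstrap models/probe\n",
              nrow(object@depth), ncol(object@depth),
              object@config@nBootstrap))
  cat(sprintf("  probe quality: %d ok, %d faulty, %d low-R2\n",
              q[["ok"]], q[["faulty_probe"]], q[["low_r2"]]))
})

#' Read a depth-matrix TSV
#'
#' The depth TSV is the contract between depth extraction and the calling
#' stages: probe columns (\code{probe_id}, \code{chrom}, \code{start},
#' \code{end}, \code{gene}, \code{transcript}, \code{exon}, \code{pool},
#' 0-based half-open coordinates) followed by one numeric column per sample.
#'
#' @param path path to the TSV.
#' @param samples optional sample sheet data.frame (restricts/annotates
#'   samples).
#' @param mode capture mode recorded in the container.
#' @param xNormalized whether the stored depths already had female chrX
#'   halved.
#' @return A \linkS4class{PanelDepth}.
#' @export
readDepthMatrix <- function(path, samples = NULL,
                            mode = c("hybridization", "pcr"),
                            xNormalized = FALSE) {
  mode <- match.arg(mode)
  if (!file.exists(path)) ioError("depth matrix not found: %s", path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  meta <- c("probe_id", "chrom", "start", "end", "gene", "transcript",
            "exon", "pool")
  miss <- setdiff(meta, colnames(df))
  if (length(miss))
    validationError("depth matrix lacks columns: %s",
                    paste(miss, collapse = ", "))
  sampleCols <- setdiff(colnames(df), meta)
  if (!length(sampleCols)) validationError("depth matrix has no sample columns")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    probe_id = df$probe_id, gene = df$gene,
    transcript = as.character(df$transcript), exon = as.character(df$exon),
    pool = as.character(df$pool))
  names(gr) <- df$probe_id
  m <- as.matrix(df[, sampleCols, drop = FALSE])
  PanelDepth(m, gr, samples = samples, mode = mode,
             xNormalized = xNormalized)
}

#' Write the depth matrix TSV
#'
#' @param pd a \linkS4class{PanelDepth}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDepthMatrix <- function(pd, path) {
  rr <- SummarizedExperiment::rowRanges(pd)
  mc <- S4Vectors::mcols(rr)
  df <- data.frame(
    probe_id = mc$probe_id,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    start = GenomicRanges::start(rr) - 1L,
    end = GenomicRanges::end(rr),
    gene = mc$gene, transcript = mc$transcript, exon = mc$exon,
    pool = mc$pool, stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(depthValues(pd), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
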