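#' Assign a read to the amplicon it overlaps most
#'
#' Implements the amplicon-capture assignment rule: among candidate
#' amplicons on the read's chromosome, pick the one with the largest overlap
#' with the aligned interval; on an exact overlap tie pick the smallest
#' amplicon; remaining ties are broken by leftmost start, then panel order,
#' so that assignment is deterministic.  Returns NA when nothing overlaps.
#'
#' @param read a length-1 \link[GenomicRanges]{GRanges} holding the aligned
#'   interval of the read.
#' @param amplicons candidate amplicon \link[GenomicRanges]{GRanges}.
#' @return Integer index into \code{amplicons}, or NA.
#' @export
assignReadToAmplicon <- function(read, amplicons) {
  idx <- assignReads(GenomicRanges::granges(read), amplicons)
  idx[1]
}

# vectorised assignment: one best amplicon index (or NA) per read
assignReads <- function(reads, amplicons) {
  hits <- GenomicRanges::findOverlaps(reads, amplicons, ignore.strand = TRUE)
  if (!length(hits))
    return(rep(NA_integer_, length(reads)))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    GenomicRanges::granges(reads)[qh], GenomicRanges::granges(amplicons)[sh]))
  # rank candidates per read: max overlap, then smallest amplicon, then
  # leftmost start, then panel order
  ord <- order(qh, -ov, GenomicRanges::width(amplicons)[sh],
               GenomicRanges::start(amplicons)[sh], sh)
  keep <- !duplicated(qh[ord])
  best <- integer(length(reads))
  best[] <- NA_integer_
  best[qh[ord][keep]] <- sh[ord][keep]
  best
}

readBamAlignments <- function(bam, sampleId, mqvMin, dropDuplicates) {
  if (!file.exists(bam))
    ioError("alignment file for sample %s not found: %s", sampleId, bam)
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (dropDuplicates) FALSE else NA)
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = mqvMin)
  tryCatch(GenomicAlignments::readGAlignments(bam, param = param),
           error = function(e) ioError("cannot read alignments for sample %s (%s): %s",
                                       sampleId, bam, conditionMessage(e)))
}

#' Probe-level read depth for amplicon (PCR) capture
#'
#' Counts, per amplicon and sample, the reads whose aligned interval is
#' assigned to that amplicon by the maximum-overlap rule
#' (\code{\link{assignReadToAmplicon}}).  Only mapped, primary,
#' non-supplementary alignments with mapping quality at least
#' \code{config@mqvMin} are counted; duplicate-marked reads are kept, since
#' amplicon libraries must not be deduplicated.
#'
#' @param bams named character vector of indexed BAM paths, names are sample
#'   ids.
#' @param probes amplicon \link[GenomicRanges]{GRanges}.
#' @param config a \linkS4class{PanelConfig}.
#' @param samples optional sample sheet data.frame.
#' @return A \linkS4class{PanelDepth} with mode "pcr".
#' @export
depthPcr <- function(bams, probes, config = panelConfig(), samples = NULL) {
  if (!length(probes)) validationError("empty probe panel")
  depth <- vapply(names(bams), function(s) {
    ga <- readBamAlignments(bams[[s]], s, config@mqvMin, dropDuplicates = FALSE)
    idx <- assignReads(GenomicRanges::granges(ga), probes)
    tabulate(idx[!is.na(idx)], nbins = length(probes))
  }, numeric(length(probes)))
  depth <- matrix(depth, nrow = length(probes),
                  dimnames = list(S4Vectors::mcols(probes)$probe_id,
                                  names(bams)))
  PanelDepth(depth, probes, samples = samples, mode = "pcr")
}

#' Probe-level read depth for hybridization capture
#'
#' For hybridization capture a read cannot be attributed to a single bait,
#' so depth is the mean per-base coverage over the probe interval; a read
#' overlapping two probes contributes to both.  Mapped, primary,
#' non-supplementary, non-duplicate alignments with mapping quality at least
#' \code{config@mqvMin} contribute coverage.
#'
#' @inheritParams depthPcr
#' @return A \linkS4class{PanelDepth} with mode "hybridization".
#' @export
depthHyb <- function(bams, probes, config = panelConfig(), samples = NULL) {
  if (!length(probes)) validationError("empty probe panel")
  chroms <- as.character(GenomicRanges::seqnames(probes))
  depth <- vapply(names(bams), function(s) {
    ga <- readBamAlignments(bams[[s]], s, config@mqvMin, dropDuplicates = TRUE)
    cov <- GenomicAlignments::coverage(ga)
    vapply(seq_along(probes), function(i) {
      ch <- chroms[i]
      if (!ch %in% names(cov)) return(0)
      rng <- IRanges::IRanges(GenomicRanges::start(probes)[i],
                              GenomicRanges::end(probes)[i])
      v <- cov[[ch]]
      # coverage Rle ends at the last aligned base; bases beyond it are 0
      len <- length(v)
      lo <- min(IRanges::start(rng), len + 1L)
      hi <- min(IRanges::end(rng), len)
      total <- if (hi >= lo)
        IRanges::viewSums(IRanges::Views(v, IRanges::IRanges(lo, hi))) else 0
      total / GenomicRanges::width(probes)[i]
    }, numeric(1))
  }, numeric(length(probes)))
  depth <- matrix(depth, nrow = length(probes),
                  dimnames = list(S4Vectors::mcols(probes)$probe_id,
                                  names(bams)))
  PanelDepth(depth, probes, samples = samples, mode = "hybridization")
}

#' Normalize chromosome X depth by gender
#'
#' Halves the chromosome X probe depths of female samples so that one copy
#' is the reference level on X for both genders; autosomal entries and male
#' samples are untouched.  Refuses to run twice, and requires a gender for
#' every sample when the panel contains chrX probes.
#'
#' @param pd a \linkS4class{PanelDepth}.
#' @return The normalized \linkS4class{PanelDepth} (\code{isXNormalized}
#'   TRUE).
#' @export
normalizeX <- function(pd) {
  if (isXNormalized(pd))
    validationError("depth matrix is already chromosome-X normalized")
  rr <- SummarizedExperiment::rowRanges(pd)
  onX <- isChrX(GenomicRanges::seqnames(rr))
  if (any(onX)) {
    gender <- SummarizedExperiment::colData(pd)$gender
    if (anyNA(gender))
      validationError("panel has chrX probes but sample(s) %s lack a gender",
        paste(colnames(pd)[is.na(gender)], collapse = ", "))
    d <- depthValues(pd)
    fem <- gender == "female"
    d[onX, fem] <- d[onX, fem] / 2
    SummarizedExperiment::assay(pd, "depth") <- d
  }
  pd@xNormalized <- TRUE
  pd
}

#' Per-sample, per-pool median depths
#'
#' The regression predictor: for each sample the median of the
#' (post-normalization) depths over the probes of each pool.  For a
#' single-pool panel this is the per-sample median depth.
#'
#' @param pd a \linkS4class{PanelDepth}.
#' @return Numeric matrix, pools in rows, samples in columns.
#' @export
sampleMedians <- function(pd) {
  pools <- probePools(pd)
  d <- depthValues(pd)
  out <- t(vapply(unique(pools), function(p) {
    rows <- pools == p
    if (!any(rows)) validationError("pool '%s' has no probes", p)
    apply(d[rows, , drop = FALSE], 2, median)
  }, numeric(ncol(d))))
  if (ncol(d) == 1L) out <- matrix(out, ncol = 1L,
                                   dimnames = list(unique(pools), colnames(d)))
  out
}
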