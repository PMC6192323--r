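#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges colData
#' @importFrom GenomeInfoDb sortSeqlevels seqnames
#' @importFrom stats median quantile cor sd rnbinom rpois runif setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Tunable parameters of the panel CNV pipeline
#'
#' Holds every threshold used by the pipeline, with the published defaults.
#' Read-depth ratios below \code{thDel} (default 0.7) count as deletion
#' evidence, above \code{thDup} (default 1.3) as duplication evidence; a
#' probe/sample cell is called non-neutral when more than \code{probCutoff}
#' (default 0.5) of the \code{nBootstrap} (default 1000) bootstrap ratios
#' cross the corresponding threshold.  The remaining slots carry the probe
#' quality cutoff (mean bootstrap R-squared \code{r2ProbeMin}, default 0.8),
#' the sample QC correlation cutoff (\code{corrMin}, default 0.7), the
#' profile cap for segmentation (\code{profileCap}, default 16), the five
#' confidence-score thresholds, and the segmentation test parameters.
#'
#' @slot nBootstrap integer, number of bootstrap regression fits per probe.
#' @slot thDel,thDup numeric, ratio thresholds bounding the copy-neutral band.
#' @slot probCutoff numeric, fraction of bootstrap ratios that must cross a
#'   threshold before a probe/sample cell is called non-neutral.
#' @slot profileCap numeric, upper limit applied to median ratios entering
#'   the segmentation profile.
#' @slot r2ProbeMin numeric, minimum mean bootstrap R-squared for a probe to
#'   be used in calling.
#' @slot corrMin numeric, minimum top-quadrant inter-sample correlation.
#' @slot mqvMin integer, minimum mapping quality for a read to be counted.
#' @slot minSamples integer, minimum number of QC-passing samples.
#' @slot probeCntMin integer, score criterion 1: probes per candidate.
#' @slot log2DelMax,log2DupMin numeric, score criterion 2 bounds on the mean
#'   log2 median ratio (defaults log2(0.6) and log2(1.4)).
#' @slot stdMax numeric, score criterion 3 bound on the SD of log2 ratios.
#' @slot ciMax numeric, score criterion 4 bound on the mean log2 CI length.
#' @slot r2ScoreMin numeric, score criterion 5 bound on the mean R-squared.
#' @slot cbsAlpha numeric, permutation p-value below which a segmentation
#'   split is accepted.
#' @slot cbsPerms integer, number of permutations per segmentation test.
#' @slot rescueProb numeric, probe-level evidence fraction that defines a
#'   "strong" signal for the consecutive-probe rescue rule.
#' @slot rngSeed integer, seed driving every stochastic step.
#' @export
setClass("PanelConfig",
  representation(
    nBootstrap = "integer",
    thDel = "numeric", thDup = "numeric",
    probCutoff = "numeric", profileCap = "numeric",
    r2ProbeMin = "numeric", corrMin = "numeric",
    mqvMin = "integer", minSamples = "integer",
    probeCntMin = "integer",
    log2DelMax = "numeric", log2DupMin = "numeric",
    stdMax = "numeric", ciMax = "numeric", r2ScoreMin = "numeric",
    cbsAlpha = "numeric", cbsPerms = "integer", rescueProb = "numeric",
    rngSeed = "integer"
  )
)

setValidity("PanelConfig", function(object) {
  msg <- character()
  num <- vapply(slotNames(object), function(s) slot(object, s), numeric(1))
  if (!all(is.finite(num))) msg <- c(msg, "all thresholds must be finite")
  if (!(object@thDel < 1 && 1 < object@thDup))
    msg <- c(msg, "thDel < 1 < thDup is required")
  if (!(object@probCutoff > 0 && object@probCutoff < 1))
    msg <- c(msg, "probCutoff must lie in (0, 1)")
  if (object@nBootstrap < 2L) msg <- c(msg, "nBootstrap must be >= 2")
  if (object@minSamples < 2L) msg <- c(msg, "minSamples must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Probe-by-sample read depth container
#'
#' Extends \linkS4class{RangedSummarizedExperiment}: rows are capture probes
#' (a \link[GenomicRanges]{GRanges} with \code{probe_id}, \code{gene},
#' \code{transcript}, \code{exon} and \code{pool} metadata columns), columns
#' are samples (colData holds \code{gender} and optionally \code{bam}), and
#' the single \code{"depth"} assay holds non-negative read depths: assigned
#' read counts for amplicon (PCR) capture, mean per-base coverage for
#' hybridization capture.
#'
#' @slot captureMode "hybridization" or "pcr".
#' @slot xNormalized logical, whether chromosome X depths of female samples
#'   have already been halved.
#' @export
setClass("PanelDepth",
  contains = "RangedSummarizedExperiment",
  representation(captureMode = "character", xNormalized = "logical")
)

setValidity("PanelDepth", function(object) {
  msg <- character()
  if (!"depth" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'depth' is required")
  else {
    d <- SummarizedExperiment::assay(object, "depth")
    if (any(!is.finite(d)) || any(d < 0))
      msg <- c(msg, "depths must be finite and non-negative")
  }
  if (!object@captureMode %in% c("hybridization", "pcr"))
    msg <- c(msg, "captureMode must be 'hybridization' or 'pcr'")
  rr <- SummarizedExperiment::rowRanges(object)
  need <- c("probe_id", "gene", "pool")
  if (!all(need %in% colnames(S4Vectors::mcols(rr))))
    msg <- c(msg, "rowRanges need probe_id, gene and pool columns")
  else if (anyDuplicated(S4Vectors::mcols(rr)$probe_id))
    msg <- c(msg, "probe_id must be unique")
  if (length(msg)) msg else TRUE
})

#' Fitted per-probe bootstrap regression models and ratio summaries
#'
#' One object per analysed cohort.  For probe t and bootstrap replicate n the
#' slots \code{slopes}/\code{intercepts}/\code{r2} hold the coefficients and
#' in-bag R-squared of the n-th resampled ordinary least squares fit of probe
#' depth against the probe's pool median depth.  Ratio summaries are
#' probe-by-sample matrices derived from the N bootstrap ratios
#' y_obs / y_pred: the median ratio, its 2.5/97.5 percentile bounds, the
#' fractions of ratios beyond the duplication/deletion thresholds, and the
#' resulting per-cell status call.
#'
#' @slot depth the \linkS4class{PanelDepth} the models were fitted to
#'   (QC-passing samples only).
#' @slot config the \linkS4class{PanelConfig} used.
#' @slot slopes,intercepts,r2 probe-by-N numeric matrices.
#' @slot meanR2 numeric, per-probe mean of the N in-bag R-squared values.
#' @slot quality character, per-probe flag: "ok", "faulty_probe" (some
#'   bootstrap slope negative) or "low_r2" (mean R-squared below cutoff).
#' @slot faultySamples logical probe-by-sample matrix; TRUE where some
#'   bootstrap model predicts a negative depth, making the cell uncallable.
#' @slot medianRatio,ciLo,ciHi,pDup,pDel numeric probe-by-sample matrices.
#' @slot status character probe-by-sample matrix with values "duplication",
#'   "neutral", "deletion" or NA for uncallable cells.
#' @export
setClass("CnvFit",
  representation(
    depth = "PanelDepth", config = "PanelConfig",
    slopes = "matrix", intercepts = "matrix", r2 = "matrix",
    meanR2 = "numeric", quality = "character",
    faultySamples = "matrix",
    medianRatio = "matrix", ciLo = "matrix", ciHi = "matrix",
    pDup = "matrix", pDel = "matrix", status = "matrix"
  )
)

setValidity("CnvFit", function(object) {
  msg <- character()
  tt <- nrow(object@depth); kk <- ncol(object@depth)
  for (s in c("medianRatio", "ciLo", "ciHi", "pDup", "pDel", "status",
              "faultySamples")) {
    m <- slot(object, s)
    if (!identical(dim(m), c(tt, kk)))
      msg <- c(msg, sprintf("slot '%s' must be %d x %d", s, tt, kk))
  }
  if (length(object@quality) != tt || length(object@meanR2) != tt)
    msg <- c(msg, "quality and meanR2 must have one entry per probe")
  bad <- !object@quality %in% c("ok", "faulty_probe", "low_r2")
  if (any(bad)) msg <- c(msg, "unknown probe quality flag")
  p <- c(object@pDup, object@pDel)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    msg <- c(msg, "pDup/pDel must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic targeted-sequencing cohort
#'
#' Describes the generative model used by \code{\link{simulateCohort}}:
#' depth(t, k) is drawn from the chosen noise model around
#' scale_k * affinity_t * copy(t, k)/2, with male chromosome X depths halved
#' at generation time.  Implanted CNVs are given as rows of the
#' \code{implants} data frame (sample, gene, first/last probe index within
#' the gene, copy number in 0/1/3/4).
#'
#' @slot nSamples integer number of samples.
#' @slot nGenes,probesPerGene integer panel layout.
#' @slot nPools integer; genes are assigned to pools round-robin.
#' @slot xGenes integer, how many of the last genes sit on chromosome X.
#' @slot scaleRange numeric length 2, per-sample median-depth scale drawn
#'   uniformly from this range.
#' @slot affinitySdLog numeric, SD of the log-normal probe affinity
#'   multipliers.
#' @slot noise "negative_binomial" or "poisson".
#' @slot dispersion numeric, extra-Poisson coefficient of variation of the
#'   negative binomial (variance mu + (dispersion*mu)^2, i.e. NB size =
#'   dispersion^-2).
#' @slot implants data.frame with columns sample, gene, fromProbe, toProbe,
#'   copy.
#' @slot genders character vector, recycled over samples.
#' @slot seed integer random seed (mandatory).
#' @export
setClass("SimSpec",
  representation(
    nSamples = "integer", nGenes = "integer", probesPerGene = "integer",
    nPools = "integer", xGenes = "integer",
    scaleRange = "numeric", affinitySdLog = "numeric",
    noise = "character", dispersion = "numeric",
    implants = "data.frame", genders = "character", seed = "integer"
  )
)

setValidity("SimSpec", function(object) {
  msg <- character()
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be positive")
  if (object@nGenes < 1L || object@probesPerGene < 1L)
    msg <- c(msg, "panel layout must be non-empty")
  if (is.na(object@seed)) msg <- c(msg, "seed is mandatory")
  if (!object@noise %in% c("negative_binomial", "poisson", "none"))
    msg <- c(msg, "noise must be 'negative_binomial', 'poisson' or 'none'")
  imp <- object@implants
  if (nrow(imp)) {
    if (!all(c("sample", "gene", "fromProbe", "toProbe", "copy") %in%
             colnames(imp)))
      msg <- c(msg, "implants need sample/gene/fromProbe/toProbe/copy")
    else {
      if (any(imp$copy %in% 2) || any(!imp$copy %in% c(0, 1, 3, 4)))
        msg <- c(msg, "implant copy numbers must be in {0, 1, 3, 4}")
      if (any(imp$fromProbe < 1 | imp$toProbe > object@probesPerGene |
              imp$fromProbe > imp$toProbe))
        msg <- c(msg, "implant probe spans must fit the gene layout")
      okGenes <- sprintf("GENE%02d", seq_len(object@nGenes))
      okSamples <- sprintf("S%02d", seq_len(object@nSamples))
      if (!all(imp$gene %in% okGenes))
        msg <- c(msg, "implant genes must exist in the panel layout")
      if (!all(imp$sample %in% okSamples))
        msg <- c(msg, "implant samples must exist in the cohort")
    }
  }
  if (length(msg)) msg else TRUE
})
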