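#' Describe a synthetic targeted-sequencing cohort
#'
#' Builds a validated \linkS4class{SimSpec}.  The generative model reflects
#' the assumption underlying the regression: the expected depth of a
#' copy-neutral probe is proportional to the sample's sequencing scale, so
#' depth(t, k) is drawn from the noise model around scale_k * affinity_t *
#' copy(t, k) / 2, with male chromosome X halved at generation.  Defaults
#' describe a realistic validation cohort: 20 samples, 50 genes of 5 probes
#' (the last two genes on chromosome X), per-sample scales uniform on
#' [80, 300] (median target depths typical of clinical panels), log-normal
#' probe affinities with SD 0.5 on the log scale (inter-probe capture
#' efficiency spread), and negative-binomial noise with a 5 percent
#' extra-Poisson coefficient of variation.
#'
#' @param nSamples number of samples (default 20).
#' @param nGenes,probesPerGene panel layout (default 50 x 5).
#' @param nPools number of probe pools, assigned to genes round-robin
#'   (default 1).
#' @param xGenes how many of the last genes sit on chromosome X (default 2).
#' @param scaleRange range of per-sample depth scales (default c(80, 300)).
#' @param affinitySdLog SD of log probe-affinity multipliers (default 0.5).
#' @param noise "negative_binomial" (default) or "poisson".
#' @param dispersion extra-Poisson coefficient of variation of the negative
#'   binomial: variance mu + (dispersion*mu)^2 (default 0.05).
#' @param implants data.frame (sample, gene, fromProbe, toProbe, copy) of
#'   CNVs to implant; \code{defaultImplants()} gives the standard set.
#' @param genders character vector recycled over samples (default
#'   alternating female/male).
#' @param seed integer seed (mandatory).
#' @return A \linkS4class{SimSpec}.
#' @export
simSpec <- function(nSamples = 20L, nGenes = 50L, probesPerGene = 5L,
                    nPools = 1L, xGenes = 2L,
                    scaleRange = c(80, 300), affinitySdLog = 0.5,
                    noise = c("negative_binomial", "poisson", "none"),
                    dispersion = 0.05,
                    implants = defaultImplants(), genders = c("female", "male"),
                    seed = 20260101L) {
  noise <- match.arg(noise)
  new("SimSpec", nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
      probesPerGene = as.integer(probesPerGene), nPools = as.integer(nPools),
      xGenes = as.integer(xGenes), scaleRange = as.numeric(scaleRange),
      affinitySdLog = affinitySdLog, noise = noise, dispersion = dispersion,
      implants = implants, genders = genders, seed = as.integer(seed))
}

#' @describeIn simSpec the default implant set: heterozygous deletions
#'   (copy 1) spanning 3 probes and a whole gene, and one-extra-copy
#'   duplications (copy 3) spanning 3 probes and a whole gene, in four
#'   distinct autosomal genes and samples.
#' @export
defaultImplants <- function() {
  data.frame(
    sample = c("S03", "S07", "S11", "S15"),
    gene = c("GENE05", "GENE12", "GENE23", "GENE31"),
    fromProbe = c(2L, 1L, 2L, 1L),
    toProbe = c(4L, 5L, 4L, 5L),
    copy = c(1, 1, 3, 3),
    stringsAsFactors = FALSE)
}

simPanel <- function(spec) {
  nP <- spec@nGenes * spec@probesPerGene
  geneIdx <- rep(seq_len(spec@nGenes), each = spec@probesPerGene)
  genes <- sprintf("GENE%02d", geneIdx)
  onX <- geneIdx > spec@nGenes - spec@xGenes
  chrom <- ifelse(onX, "X", as.character((geneIdx - 1L) %% 22L + 1L))
  probeInGene <- rep(seq_len(spec@probesPerGene), times = spec@nGenes)
  start <- geneIdx * 1000000L + (probeInGene - 1L) * 500L
  pools <- sprintf("pool%d", (geneIdx - 1L) %% spec@nPools + 1L)
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, width = 120L),
    probe_id = sprintf("%s_P%d", genes, probeInGene),
    gene = genes,
    transcript = sprintf("NM_%06d", geneIdx),
    exon = sprintf("EX%d", probeInGene),
    pool = pools)
}

#' Simulate a cohort with known implanted CNVs
#'
#' Draws a probe-by-sample depth matrix under the \linkS4class{SimSpec}
#' generative model and returns it together with the ground truth.  Fixed
#' seed implies a bit-identical cohort.
#'
#' @param spec a \linkS4class{SimSpec}.
#' @return A list: \code{depth} (a \linkS4class{PanelDepth}, raw depths, not
#'   yet chrX-normalized), \code{truth} (data.frame of implanted candidates
#'   with genomic spans), \code{scale} (per-sample scale factors),
#'   \code{affinity} (per-probe multipliers), \code{copy} (probe-by-sample
#'   true copy matrix).
#' @export
simulateCohort <- function(spec) {
  probes <- simPanel(spec)
  # simPanel emits probes gene-by-gene; keep genomic sort for the container
  nP <- length(probes)
  sampleIds <- sprintf("S%02d", seq_len(spec@nSamples))
  genders <- rep(spec@genders, length.out = spec@nSamples)
  mc <- S4Vectors::mcols(probes)

  withLocalSeed(spec@seed, {
    scale <- runif(spec@nSamples, spec@scaleRange[1], spec@scaleRange[2])
    affinity <- exp(rnorm(nP, 0, spec@affinitySdLog))

    copy <- matrix(2, nP, spec@nSamples,
                   dimnames = list(mc$probe_id, sampleIds))
    imp <- spec@implants
    for (i in seq_len(nrow(imp))) {
      if (!imp$sample[i] %in% sampleIds)
        validationError("implant references unknown sample %s", imp$sample[i])
      rows <- which(mc$gene == imp$gene[i])
      if (!length(rows))
        validationError("implant references unknown gene %s", imp$gene[i])
      rows <- rows[imp$fromProbe[i]:imp$toProbe[i]]
      copy[rows, imp$sample[i]] <- imp$copy[i]
    }

    onX <- isChrX(GenomicRanges::seqnames(probes))
    male <- genders == "male"
    mu <- outer(affinity, scale) * copy / 2
    mu[onX, male] <- mu[onX, male] / 2  # one X in males, before any tool step

    depth <- matrix(drawNoise(as.vector(mu), spec), nP, spec@nSamples,
                    dimnames = dimnames(copy))
  })

  samples <- data.frame(sample_id = sampleIds, gender = genders,
                        bam = NA_character_, stringsAsFactors = FALSE)
  pd <- PanelDepth(depth, probes, samples = samples, mode = "pcr")

  truth <- spec@implants
  truth$cnv_type <- ifelse(truth$copy < 2, "deletion", "duplication")
  span <- lapply(seq_len(nrow(truth)), function(i) {
    rows <- which(mc$gene == truth$gene[i])[truth$fromProbe[i]:truth$toProbe[i]]
    c(min(GenomicRanges::start(probes)[rows]) - 1L,
      max(GenomicRanges::end(probes)[rows]))
  })
  truth$chrom <- vapply(truth$gene, function(g)
    as.character(GenomicRanges::seqnames(probes))[which(mc$gene == g)[1]],
    character(1))
  truth$start <- vapply(span, `[`, numeric(1), 1)
  truth$end <- vapply(span, `[`, numeric(1), 2)

  list(depth = pd, truth = truth, scale = setNames(scale, sampleIds),
       affinity = setNames(affinity, mc$probe_id), copy = copy)
}

drawNoise <- function(mu, spec) {
  if (spec@noise == "none" || all(mu == 0)) return(mu)
  out <- numeric(length(mu))
  pos <- mu > 0
  if (spec@noise == "poisson" ) {
    out[pos] <- rpois(sum(pos), mu[pos])
  } else if (spec@dispersion <= 0) {
    out[pos] <- rpois(sum(pos), mu[pos])
  } else {
    size <- 1 / spec@dispersion^2
    out[pos] <- rnbinom(sum(pos), mu = mu[pos], size = size)
  }
  out
}

#' Write a complete fixture bundle for the pipeline
#'
#' Simulates the cohort and writes probe design, sample sheet, depth matrix,
#' truth table and configuration into \code{dir} — a complete, re-loadable
#' input set for the command-line pipeline.
#'
#' @param spec a \linkS4class{SimSpec}.
#' @param dir output directory (created if needed).
#' @param config \linkS4class{PanelConfig} written alongside (its
#'   \code{rngSeed} is set to the spec seed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
writeFixtureBundle <- function(spec, dir, config = panelConfig()) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0)
    ioError("cannot write fixture bundle to %s", dir)
  sim <- simulateCohort(spec)
  config@rngSeed <- spec@seed
  paths <- c(
    probes = file.path(dir, "probes.tsv"),
    samples = file.path(dir, "samples.tsv"),
    depth = file.path(dir, "depth.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml"))
  writeProbeFile(SummarizedExperiment::rowRanges(sim$depth), paths["probes"])
  write.table(as.data.frame(SummarizedExperiment::colData(sim$depth))[,
                c("sample_id", "gender")],
              paths["samples"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeDepthMatrix(sim$depth, paths["depth"])
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeConfig(config, paths["config"])
  invisible(paths)
}

#' Write a toy SAM file of synthetic reads
#'
#' Minimal alignment writer used to exercise the depth-extraction module
#' without real sequencing data: each row of \code{reads} becomes one
#' perfectly-matched single-end alignment.  Convert with
#' \code{Rsamtools::asBam} to obtain an indexed BAM.
#'
#' @param reads data.frame with columns \code{chrom}, \code{pos} (1-based
#'   leftmost), \code{len}, \code{mapq}, and optionally \code{flag}
#'   (default 0) and \code{qname}.
#' @param path output SAM path.
#' @param seqlengths named integer vector of reference lengths; defaults to
#'   a generous bound per chromosome present.
#' @return \code{path}, invisibly.
#' @export
writeToySam <- function(reads, path, seqlengths = NULL) {
  if (is.null(seqlengths)) {
    seqlengths <- vapply(split(reads$pos + reads$len, reads$chrom),
                         function(x) max(x) + 1000, numeric(1))
  }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  reads <- reads[order(match(reads$chrom, names(seqlengths)), reads$pos), ]
  flag <- if ("flag" %in% colnames(reads)) reads$flag else 0L
  qname <- if ("qname" %in% colnames(reads)) reads$qname else
    sprintf("read%04d", seq_len(nrow(reads)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                  qname, flag, reads$chrom, reads$pos, reads$mapq,
                  reads$len, strrep("A", reads$len))
  writeLines(c(hdr, body), path)
  invisible(path)
}
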