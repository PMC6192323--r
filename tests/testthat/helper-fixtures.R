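# shared fixtures, all generated in code

# small configuration for fast unit tests (fewer bootstraps, fixed seed)
tinyConfig <- function(...) {
  panelConfig(nBootstrap = 200L, rngSeed = 7L, ...)
}

# a rank-one (noiseless) cohort: depth = affinity_t * scale_k, so every
# probe is exactly linear in the per-sample median with zero residual
rankOnePd <- function(affinity = c(1, 2, 4, 3, 5),
                      scale = c(50, 80, 110, 140, 170, 200, 230, 260),
                      chrom = rep("1", length(affinity)),
                      gender = rep(c("female", "male"),
                                   length.out = length(scale))) {
  tn <- length(affinity)
  probes <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = seq_len(tn) * 1000 + 1, width = 100),
    probe_id = sprintf("P%02d", seq_len(tn)),
    gene = sprintf("G%d", (seq_len(tn) - 1) %/% 5 + 1),
    transcript = NA_character_, exon = NA_character_,
    pool = "pool1")
  depth <- outer(affinity, scale)
  colnames(depth) <- sprintf("S%02d", seq_along(scale))
  samples <- data.frame(sample_id = colnames(depth), gender = gender,
                        bam = NA_character_, stringsAsFactors = FALSE)
  PanelDepth(depth, probes, samples = samples, mode = "pcr")
}

# write a probe design TSV from a data.frame of BED-like rows
writeProbeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

probeDesignDf <- function() {
  data.frame(
    chrom = c("1", "1", "2", "2", "X"),
    start = c(100L, 500L, 100L, 700L, 300L),
    end = c(220L, 650L, 250L, 820L, 420L),
    gene = c("GBA", "GBA", "IDUA", "IDUA", "OTC"),
    transcript = "NM_000000", exon = paste0("EX", 1:5),
    pool = c("pool1", "pool2", "pool1", "pool2", "pool1"),
    stringsAsFactors = FALSE)
}

writeSampleTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# convert a toy SAM (from writeToySam) to an indexed BAM in tempdir
samToBam <- function(samPath) {
  dest <- tempfile()
  Rsamtools::asBam(samPath, dest, overwrite = TRUE, indexDestination = TRUE)
}

# two-amplicon toy panel on chromosome 1 used by the depth tests
toyAmplicons <- function() {
  GenomicRanges::GRanges(
    seqnames = "1",
    ranges = IRanges::IRanges(start = c(101, 201), end = c(220, 300)),
    probe_id = c("AMP1", "AMP2"), gene = c("GBA", "GBA"),
    transcript = NA_character_, exon = c("EX1", "EX2"), pool = "pool1")
}
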