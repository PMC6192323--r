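test_that("a flat profile yields exactly one segment", {
  segs <- cbsSegment(rep(1, 9), tinyConfig())
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start, 1L)
  expect_equal(segs$end, 9L)
  expect_equal(segs$mean_ratio, 1)

  # single-probe profile: one segment, no test
  expect_equal(nrow(cbsSegment(2, tinyConfig())), 1L)
})

test_that("a clear step is segmented at its edges", {
  # long enough that the permutation test has power at alpha 0.01
  set.seed(12)
  vals <- c(rep(1, 12), rep(0.5, 9), rep(1, 12)) * exp(rnorm(33, 0, 0.01))
  segs <- cbsSegment(vals, panelConfig(cbsPerms = 500L, rngSeed = 5L))
  expect_equal(nrow(segs), 3L)
  expect_equal(segs$start, c(1L, 13L, 22L))
  expect_equal(segs$end, c(12L, 21L, 33L))
  expect_lt(segs$mean_ratio[2], 0.7)
  expect_gt(segs$mean_ratio[1], 0.9)
})

test_that("segmentation equals the exhaustive-search oracle on short profiles", {
  cfg <- panelConfig(cbsPerms = 300L, rngSeed = 17L)
  set.seed(802)
  for (rep in 1:25) {
    L <- sample(3:12, 1)
    vals <- exp(rnorm(L, 0, 0.15))
    if (rep %% 2 == 0) {      # implant a step in half the profiles
      a <- sample(seq_len(L - 1), 1)
      b <- sample((a + 1):L, 1)
      vals[a:b] <- vals[a:b] * sample(c(0.5, 1.6), 1)
    }
    got <- cbsSegment(vals, cfg)
    want <- oracleSegment(vals, cfg)
    expect_equal(got$start, want$start, info = paste("profile", rep))
    expect_equal(got$end, want$end, info = paste("profile", rep))
  }
})

test_that("median ratios above the cap enter the profile at the cap", {
  expect_equal(capRatios(c(0.5, 1, 20, 16, 15.9)),
               c(0.5, 1, 16, 16, 15.9))
  expect_equal(capRatios(20, cap = panelConfig()@profileCap), 16)
})

test_that("segments are classified and merged by strict thresholds", {
  cfg <- panelConfig()
  segs <- data.frame(start = c(1L, 4L), end = c(3L, 6L), n = c(3L, 3L),
                     mean_ratio = c(0.5, 0.55))
  merged <- mergeSegments(segs, cfg)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$status, "deletion")
  expect_equal(merged$mean_ratio, mean(c(0.5, 0.55)))
  expect_equal(merged$n, 6L)

  # a neutral gap is never bridged
  segs <- data.frame(start = c(1L, 4L, 7L), end = c(3L, 6L, 9L), n = 3L,
                     mean_ratio = c(0.5, 1.0, 0.5))
  merged <- mergeSegments(segs, cfg)
  expect_equal(nrow(merged), 3L)
  expect_equal(merged$status, c("deletion", "neutral", "deletion"))

  # boundary: exactly 0.7 (or 1.3) is neutral
  segs <- data.frame(start = 1L, end = 3L, n = 3L, mean_ratio = 0.7)
  expect_equal(mergeSegments(segs, cfg)$status, "neutral")
  segs$mean_ratio <- 1.3
  expect_equal(mergeSegments(segs, cfg)$status, "neutral")
})

test_that("rescue emits maximal runs of two or more strong signals", {
  cfg <- panelConfig()
  st <- c("neutral", "deletion", "deletion", "neutral")
  pDel <- c(0, 0.9, 0.8, 0)
  runs <- rescueRuns(st, pDup = rep(0, 4), pDel = pDel, config = cfg)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$start, 2L)
  expect_equal(runs$end, 3L)
  expect_equal(runs$status, "deletion")

  # an isolated single strong probe is not rescued
  st <- c("neutral", "deletion", "neutral", "neutral")
  runs <- rescueRuns(st, rep(0, 4), c(0, 1, 0, 0), config = cfg)
  expect_equal(nrow(runs), 0L)

  # runs already inside a same-type candidate are not re-emitted
  st <- c("deletion", "deletion", "neutral", "neutral")
  existing <- data.frame(start = 1L, end = 2L, status = "deletion")
  runs <- rescueRuns(st, rep(0, 4), c(0.9, 0.9, 0, 0), existing, cfg)
  expect_equal(nrow(runs), 0L)
  # ... but an opposite-type overlap does not block
  existing$status <- "duplication"
  runs <- rescueRuns(st, rep(0, 4), c(0.9, 0.9, 0, 0), existing, cfg)
  expect_equal(nrow(runs), 1L)
})

test_that("copy numbers derive from ratios and the chromosome context", {
  expect_equal(estimateCopyNumber(c(0.5, 0.5, 0.5))$raw, 1.0)
  expect_equal(estimateCopyNumber(c(0.4, 0.6))$raw, 1.0)
  expect_equal(estimateCopyNumber(c(1.5, 1.5))$raw, 3.0)
  expect_equal(estimateCopyNumber(1.0, multipliers = 1)$raw, 1.0)  # male chrX
  expect_equal(estimateCopyNumber(c(1.4, 1.6))$rounded, 3)
})

test_that("an implanted deletion yields exactly one overlapping candidate", {
  spec <- simSpec(nSamples = 16L, nGenes = 10L, probesPerGene = 5L,
                  xGenes = 0L, dispersion = 0.03,
                  implants = data.frame(sample = "S04", gene = "GENE03",
                                        fromProbe = 2L, toProbe = 4L,
                                        copy = 1),
                  seed = 404L)
  sim <- simulateCohort(spec)
  fit <- fitProbeModels(normalizeX(sim$depth),
                        tinyConfig(cbsPerms = 300L))
  cands <- callCnvs(fit)
  hit <- cands[cands$sample_id == "S04" & cands$gene == "GENE03", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$cnv_type, "deletion")
  # overlaps the implanted span (member probes may be masked by the
  # probe-quality rules, so containment is not guaranteed)
  expect_lte(hit$start, sim$truth$end[1])
  expect_gte(hit$end, sim$truth$start[1])
  expect_true(hit$copy_number_raw < 1.5)
  # candidates never span gene boundaries
  expect_true(all(cands$gene %in% sprintf("GENE%02d", 1:10)))
})

test_that("masked probes are skipped and consecutiveness is re-evaluated", {
  # build a fit-like scenario through the public pipeline: a faulty probe
  # inside a gene must not break candidate construction
  spec <- simSpec(nSamples = 16L, nGenes = 6L, probesPerGene = 5L,
                  xGenes = 0L, dispersion = 0.03,
                  implants = data.frame(sample = "S02", gene = "GENE02",
                                        fromProbe = 1L, toProbe = 5L,
                                        copy = 3),
                  seed = 77L)
  sim <- simulateCohort(spec)
  d <- depthValues(sim$depth)
  # sabotage one probe of GENE02 so it is excluded from calling
  sab <- which(S4Vectors::mcols(
    SummarizedExperiment::rowRanges(sim$depth))$probe_id == "GENE02_P3")
  d[sab, ] <- 1500 - 4 * sampleMedians(sim$depth)[1, ]
  pd <- PanelDepth(pmax(d, 0), SummarizedExperiment::rowRanges(sim$depth),
                   as.data.frame(SummarizedExperiment::colData(sim$depth))[1:3],
                   mode = "pcr")
  fit <- fitProbeModels(normalizeX(pd), tinyConfig(cbsPerms = 300L))
  expect_equal(unname(probeFlags(fit)[sab]), "faulty_probe")
  cands <- callCnvs(fit)
  hit <- cands[cands$sample_id == "S02" & cands$gene == "GENE02", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$cnv_type, "duplication")
  expect_equal(hit$n_probes, 4L)   # the faulty probe is not a member
})

test_that("null cohorts produce few or no candidates", {
  spec <- simSpec(nSamples = 10L, nGenes = 10L, probesPerGene = 5L,
                  xGenes = 0L, implants = defaultImplants()[0, ],
                  seed = 505L)
  sim <- simulateCohort(spec)
  fit <- fitProbeModels(normalizeX(sim$depth),
                        tinyConfig(cbsPerms = 300L))
  cands <- callCnvs(fit)
  expect_lte(nrow(cands), 2L)
})
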