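test_that("a noiseless null cohort is exactly rank one and all-neutral", {
  spec <- simSpec(nSamples = 8L, nGenes = 6L, probesPerGene = 5L,
                  xGenes = 0L, noise = "none",
                  implants = defaultImplants()[0, ], seed = 1L)
  sim <- simulateCohort(spec)
  d <- depthValues(sim$depth)
  expect_equal(d, outer(sim$affinity, sim$scale) *
                 matrix(1, nrow(d), ncol(d)) , tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(qr(d)$rank, 1L)

  fit <- fitProbeModels(normalizeX(sim$depth), tinyConfig())
  expect_true(all(probeFlags(fit) == "ok"))
  expect_true(all(probeCalls(fit) == "neutral"))
})

test_that("implants scale the expected depth by copy/2", {
  imp <- data.frame(sample = "S02", gene = "GENE02",
                    fromProbe = 2L, toProbe = 4L, copy = 1)
  spec <- simSpec(nSamples = 6L, nGenes = 4L, probesPerGene = 5L,
                  xGenes = 0L, noise = "none", implants = imp, seed = 2L)
  sim <- simulateCohort(spec)
  d <- depthValues(sim$depth)
  rows <- which(S4Vectors::mcols(
    SummarizedExperiment::rowRanges(sim$depth))$gene == "GENE02")[2:4]
  neutral <- outer(sim$affinity[rows], sim$scale)
  expect_equal(unname(d[rows, "S02"]), unname(neutral[, 2]) / 2)
  expect_equal(unname(d[rows, "S01"]), unname(neutral[, 1]))
  expect_equal(sim$truth$cnv_type, "deletion")
  expect_equal(sim$copy[rows, "S02"], setNames(rep(1, 3),
               rownames(sim$copy)[rows]))
})

test_that("male chromosome X depth is generated at half scale", {
  spec <- simSpec(nSamples = 6L, nGenes = 5L, probesPerGene = 2L,
                  xGenes = 2L, noise = "none",
                  implants = defaultImplants()[0, ],
                  genders = c("female", "male"), seed = 3L)
  sim <- simulateCohort(spec)
  d <- depthValues(sim$depth)
  onX <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(sim$depth))) == "X"
  male <- SummarizedExperiment::colData(sim$depth)$gender == "male"
  neutral <- outer(sim$affinity, sim$scale)
  expect_equal(unname(d[onX, male]), unname(neutral[onX, male] / 2))
  expect_equal(unname(d[onX, !male]), unname(neutral[onX, !male]))
})

test_that("fixed seeds reproduce cohorts and bundles byte-identically", {
  imp <- data.frame(sample = "S02", gene = "GENE03",
                    fromProbe = 1L, toProbe = 2L, copy = 3)
  spec <- simSpec(nSamples = 8L, nGenes = 5L, implants = imp, seed = 42L)
  d1 <- depthValues(simulateCohort(spec)$depth)
  d2 <- depthValues(simulateCohort(spec)$depth)
  expect_identical(d1, d2)
  d3 <- depthValues(simulateCohort(simSpec(nSamples = 8L, nGenes = 5L,
                                           implants = imp,
                                           seed = 43L))$depth)
  expect_false(identical(d1, d3))

  dir1 <- file.path(tempdir(), "bundleA")
  dir2 <- file.path(tempdir(), "bundleB")
  writeFixtureBundle(spec, dir1)
  writeFixtureBundle(spec, dir2)
  for (f in c("probes.tsv", "samples.tsv", "depth.tsv", "truth.tsv",
              "config.yaml")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})

test_that("fixture bundles are complete, re-loadable pipeline inputs", {
  spec <- simSpec(nSamples = 8L, nGenes = 5L, seed = 9L,
                  implants = data.frame(sample = "S04", gene = "GENE02",
                                        fromProbe = 2L, toProbe = 3L,
                                        copy = 1))
  dir <- file.path(tempdir(), "bundleC")
  paths <- writeFixtureBundle(spec, dir)
  expect_true(all(file.exists(paths)))

  probes <- parseProbeFile(paths[["probes"]])
  expect_length(probes, 25)
  samples <- parseSampleSheet(paths[["samples"]])
  expect_equal(nrow(samples), 8L)
  pd <- readDepthMatrix(paths[["depth"]], samples = samples, mode = "pcr")
  expect_equal(dim(pd), c(25L, 8L))
  # depth TSV round-trips the simulated matrix exactly
  expect_equal(depthValues(pd), depthValues(simulateCohort(spec)$depth))
  cfg <- loadConfig(paths[["config"]])
  expect_equal(cfg@rngSeed, 9L)
  truth <- read.delim(paths[["truth"]])
  expect_equal(nrow(truth), nrow(spec@implants))
})

test_that("negative-binomial noise has the configured dispersion", {
  spec <- simSpec(nSamples = 200L, nGenes = 10L, probesPerGene = 5L,
                  xGenes = 0L, implants = defaultImplants()[0, ],
                  dispersion = 0.1, scaleRange = c(200, 200), seed = 6L)
  sim <- simulateCohort(spec)
  d <- depthValues(sim$depth)
  mu <- sim$affinity * 200
  cv <- apply(d / mu, 1, sd)
  wantCv <- sqrt(1 / mu + 0.1^2)   # Poisson floor plus extra-Poisson CV
  expect_equal(mean(cv), mean(wantCv), tolerance = 0.1)
})

test_that("an infeasible simulation layout is rejected", {
  expect_error(simSpec(nGenes = 0L), "non-empty")
  expect_error(simSpec(implants = data.frame(
    sample = "S01", gene = "GENE01", fromProbe = 1L, toProbe = 9L,
    copy = 1)), "spans")
  expect_error(simSpec(implants = data.frame(
    sample = "S01", gene = "GENE01", fromProbe = 1L, toProbe = 2L,
    copy = 2)), "copy numbers")
})

test_that("a pure-noise sample fails QC end to end", {
  spec <- simSpec(nSamples = 10L, nGenes = 10L, probesPerGene = 5L,
                  xGenes = 0L, implants = defaultImplants()[0, ],
                  seed = 21L)
  sim <- simulateCohort(spec)
  d <- depthValues(sim$depth)
  set.seed(22)
  d[, "S05"] <- runif(nrow(d), 10, 400)   # no probe structure at all
  pd <- PanelDepth(d, SummarizedExperiment::rowRanges(sim$depth),
                   as.data.frame(SummarizedExperiment::colData(sim$depth))[1:3],
                   mode = "pcr")
  res <- suppressWarnings(
    filterSamples(sampleCorrelations(pd), panelConfig(), mode = "pcr"))
  expect_equal(res$fail, "S05")
  expect_length(res$pass, 9L)
})
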