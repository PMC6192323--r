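test_that("noiseless proportional probes fit exactly with R-squared one", {
  pd <- rankOnePd(affinity = c(1, 2, 4, 3, 5))
  # pool median affinity is 3, so probe 3 (affinity 4) has slope 4/3, and a
  # probe with affinity 2*3 would have slope exactly 2
  pd2 <- rankOnePd(affinity = c(1, 2, 6, 3, 5))  # median still 3
  fit <- fitProbeModels(pd2, tinyConfig())
  expect_equal(unname(fit@slopes["P03", ]), rep(2, 200))
  expect_equal(unname(fit@intercepts["P03", ]), rep(0, 200),
               tolerance = 1e-8)
  expect_equal(unname(fit@r2["P03", ]), rep(1, 200))
  expect_equal(unname(fit@quality), rep("ok", 5))
  # every ratio is exactly 1: all cells neutral with degenerate CIs
  expect_equal(unname(ratioMedians(fit)), matrix(1, 5, 8), tolerance = 1e-12)
  expect_true(all(probeCalls(fit) == "neutral"))
})

test_that("uninformative probes are flagged low_r2, anti-proportional faulty", {
  scale <- seq(60, 345, by = 15)            # 20 samples
  pd <- rankOnePd(affinity = c(1, 2, 3, 4, 5, 3, 2, 4, 3, 1, 5),
                  chrom = rep("1", 11), scale = scale,
                  gender = rep("female", 20))
  d <- depthValues(pd)
  m0 <- sampleMedians(pd)[1, ]
  set.seed(31)
  # weak but clearly positive relation: R-squared well under 0.8 while the
  # slope stays many standard errors above zero
  d[6, ] <- pmax(0.5 * m0 + rnorm(20, 0, 0.8 * sd(0.5 * m0)), 1)
  d[7, ] <- 100 + rnorm(20, 0, 2)           # depth unrelated to scale
  d[8, ] <- pmax(2000 - 4 * m0, 0)          # anti-proportional
  pd2 <- PanelDepth(d, SummarizedExperiment::rowRanges(pd),
                    as.data.frame(SummarizedExperiment::colData(pd))[1:3],
                    mode = "pcr")
  fit <- fitProbeModels(pd2, tinyConfig())
  expect_equal(unname(fit@quality[6]), "low_r2")
  expect_lt(fit@meanR2[6], 0.8)
  expect_true(all(fit@slopes[6, ] > 0))
  # pure noise is excluded too (low R-squared, and typically some negative
  # resampled slopes as well)
  expect_true(fit@quality[7] != "ok")
  expect_lt(fit@meanR2[7], 0.8)
  expect_equal(unname(fit@quality[8]), "faulty_probe")
  expect_true(any(fit@slopes[8, ] < 0))
})

test_that("samples with negative predicted depth are faulty for that probe", {
  # probe depth = median - 100 for the colinear samples, plus one sample
  # whose median (50) sits below the x-intercept: predictions there are
  # negative for every resample that omits it
  scale <- c(50, 120, 150, 180, 210, 240, 270, 300)
  pd <- rankOnePd(affinity = c(1, 1, 1, 1, 1), scale = scale)
  d <- depthValues(pd)  # every depth = scale, median = scale
  d[3, ] <- pmax(scale - 100, 0)
  pd2 <- PanelDepth(d, SummarizedExperiment::rowRanges(pd),
                    as.data.frame(SummarizedExperiment::colData(pd))[1:3],
                    mode = "pcr")
  fit <- fitProbeModels(pd2, tinyConfig())
  expect_true(fit@faultySamples["P03", "S01"])
  expect_false(any(fit@faultySamples["P03", -1]))
  expect_true(is.na(ratioMedians(fit)["P03", "S01"]))  # cell uncallable
  # a clean proportional probe is never faulty for any sample
  expect_false(any(fit@faultySamples["P01", ]))
})

test_that("ratio summaries implement the evidence-fraction decision rule", {
  cfg <- panelConfig()

  s <- summarizeRatios(rep(0.5, 1000), cfg)   # observed half the prediction
  expect_equal(s$pDel, 1)
  expect_equal(s$status, "deletion")
  expect_equal(s$median, 0.5)

  s <- summarizeRatios(c(rep(1.5, 600), rep(1.0, 400)), cfg)
  expect_equal(s$pDup, 0.6)                   # 600 of 1000 above 1.3
  expect_equal(s$status, "duplication")

  s <- summarizeRatios(rep(1, 1000), cfg)
  expect_equal(s$pDup, 0)
  expect_equal(s$pDel, 0)
  expect_equal(s$status, "neutral")

  # exactly-at-threshold ratios are not evidence (strict inequalities)
  s <- summarizeRatios(rep(1.3, 1000), cfg)
  expect_equal(s$pDup, 0)

  # undefined ratios (zero predicted depth) shrink the denominator
  s <- summarizeRatios(c(rep(2, 30), rep(Inf, 70)), cfg)
  expect_equal(s$pDup, 1)
})

test_that("bootstrap fits match an lm-based oracle at small N", {
  pd <- rankOnePd(affinity = c(1.2, 2.5, 3.1, 0.7, 1.9),
                  scale = c(60, 95, 130, 170, 210, 250, 280, 310))
  d <- depthValues(pd)
  set.seed(123)
  d <- d * matrix(rlnorm(length(d), 0, 0.08), nrow(d))
  pd2 <- PanelDepth(d, SummarizedExperiment::rowRanges(pd),
                    as.data.frame(SummarizedExperiment::colData(pd))[1:3],
                    mode = "pcr")
  cfg <- panelConfig(nBootstrap = 5L, rngSeed = 99L)
  fit <- fitProbeModels(pd2, cfg)
  oracle <- oracleBootstrap(pd2, cfg)
  for (t in 1:5) {
    expect_equal(unname(fit@slopes[t, ]), unname(oracle[[t]]$slopes),
                 tolerance = 1e-9)
    expect_equal(unname(fit@intercepts[t, ]), unname(oracle[[t]]$intercepts),
                 tolerance = 1e-9)
    expect_equal(unname(fit@r2[t, ]), unname(oracle[[t]]$r2),
                 tolerance = 1e-9)
    # ratio summaries recomputed from the oracle's raw ratios
    for (k in 1:8) {
      r <- oracle[[t]]$ratios[, k]
      if (any(slot(fit, "faultySamples")[t, k])) next
      expect_equal(unname(ratioMedians(fit)[t, k]), median(r),
                   tolerance = 1e-9)
      expect_equal(unname(fit@pDup[t, k]), mean(r > 1.3), tolerance = 1e-12)
      expect_equal(unname(fit@ciLo[t, k]), unname(quantile(r, 0.025)),
                   tolerance = 1e-9)
    }
  }
})

test_that("model fitting is bit-reproducible under a fixed seed", {
  pd <- rankOnePd()
  d <- depthValues(pd)
  set.seed(77)
  d <- d * matrix(rlnorm(length(d), 0, 0.1), nrow(d))
  pd2 <- PanelDepth(d, SummarizedExperiment::rowRanges(pd),
                    as.data.frame(SummarizedExperiment::colData(pd))[1:3],
                    mode = "pcr")
  f1 <- fitProbeModels(pd2, tinyConfig())
  f2 <- fitProbeModels(pd2, tinyConfig())
  expect_identical(f1@slopes, f2@slopes)
  expect_identical(ratioMedians(f1), ratioMedians(f2))
  f3 <- fitProbeModels(pd2, panelConfig(nBootstrap = 200L, rngSeed = 8L))
  expect_false(identical(f1@slopes, f3@slopes))
})

test_that("mean bootstrap slopes recover simulated probe affinities", {
  spec <- simSpec(nSamples = 12L, nGenes = 8L, probesPerGene = 5L,
                  xGenes = 0L, implants = defaultImplants()[0, ],
                  seed = 301L)
  sim <- simulateCohort(spec)
  fit <- fitProbeModels(normalizeX(sim$depth), tinyConfig())
  med <- sampleMedians(normalizeX(sim$depth))[1, ]
  cstar <- mean(med / sim$scale)
  meanSlope <- rowMeans(fit@slopes)
  se <- apply(fit@slopes, 1, sd)
  covered <- abs(meanSlope - sim$affinity / cstar) <= 3 * se
  expect_gte(mean(covered), 0.9)
})

test_that("fitting refuses cohorts below the minimum sample count", {
  pd <- rankOnePd(scale = c(50, 80, 110, 140, 170))
  expect_error(fitProbeModels(pd, tinyConfig()), class = "pcnv_qc_error")
})
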