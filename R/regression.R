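# One probe's bootstrap: draw N resamples of the K (median, depth) pairs
# with replacement and fit ordinary least squares depth = a*median + b on
# each.  Resample rows with zero predictor variance cannot be fitted and are
# redrawn up to maxRedraw times; rows that stay degenerate are returned as
# NA (the caller marks the probe faulty).  The index matrix is drawn as
# matrix(sample.int(K, N*K, replace = TRUE), N, K) -- row n is replicate n
# -- which is the convention the test oracles reproduce.
bootFitProbe <- function(m, y, N, maxRedraw = 10L) {
  K <- length(m)
  idx <- matrix(sample.int(K, N * K, replace = TRUE), N, K)
  x <- matrix(m[idx], N, K)
  degenerate <- function(xm) matrixStatsRowVarZero(xm)
  bad <- degenerate(x)
  tries <- 0L
  while (any(bad) && tries < maxRedraw) {
    n2 <- sum(bad)
    idx2 <- matrix(sample.int(K, n2 * K, replace = TRUE), n2, K)
    idx[bad, ] <- idx2
    x[bad, ] <- m[idx2]
    bad <- degenerate(x)
    tries <- tries + 1L
  }
  yb <- matrix(y[idx], N, K)
  sx <- rowSums(x); sy <- rowSums(yb)
  sxx <- rowSums(x * x); syy <- rowSums(yb * yb); sxy <- rowSums(x * yb)
  den <- K * sxx - sx^2
  slope <- (K * sxy - sx * sy) / den
  intercept <- (sy - slope * sx) / K
  sst <- syy - sy^2 / K
  sse <- sst - slope^2 * (sxx - sx^2 / K)
  r2 <- ifelse(sst <= 0, 1, pmax(0, pmin(1, 1 - sse / sst)))
  slope[bad] <- NA; intercept[bad] <- NA; r2[bad] <- NA
  list(slopes = slope, intercepts = intercept, r2 = r2)
}

matrixStatsRowVarZero <- function(x) {
  rng <- x[, 1]
  lo <- rng; hi <- rng
  for (j in seq_len(ncol(x))[-1]) {
    lo <- pmin(lo, x[, j]); hi <- pmax(hi, x[, j])
  }
  lo == hi
}

#' Summarise a vector of bootstrap read-depth ratios
#'
#' Given the N bootstrap ratios of one probe in one sample, computes the
#' median ratio, its empirical 95 percent interval (2.5/97.5 percentiles),
#' the evidence fractions p_dup (ratios above \code{thDup}) and p_del
#' (ratios below \code{thDel}), and the resulting status call.  Non-finite
#' ratios (from zero predicted depth) are dropped and the denominator
#' reduced accordingly.
#'
#' @param ratios numeric vector of bootstrap ratios.
#' @param config a \linkS4class{PanelConfig}.
#' @return A list: \code{median}, \code{ciLo}, \code{ciHi}, \code{pDup},
#'   \code{pDel}, \code{status}.
#' @export
summarizeRatios <- function(ratios, config = panelConfig()) {
  r <- ratios[is.finite(ratios)]
  if (!length(r))
    return(list(median = NA_real_, ciLo = NA_real_, ciHi = NA_real_,
                pDup = NA_real_, pDel = NA_real_, status = NA_character_))
  q <- quantile(r, c(0.025, 0.5, 0.975), names = FALSE)
  pDup <- mean(r > config@thDup)
  pDel <- mean(r < config@thDel)
  status <- if (pDup > config@probCutoff) "duplication"
            else if (pDel > config@probCutoff) "deletion" else "neutral"
  list(median = q[2], ciLo = q[1], ciHi = q[3],
       pDup = pDup, pDel = pDel, status = status)
}

#' Fit the bootstrapped per-probe regression models
#'
#' For every probe, fits \code{config@nBootstrap} resampled ordinary least
#' squares regressions of probe depth on the probe's pool median depth
#' across the QC-passing samples, flags probe quality (any negative
#' bootstrap slope: "faulty_probe"; mean in-bag R-squared below
#' \code{config@r2ProbeMin}: "low_r2"), flags per-sample faulty cells (any
#' bootstrap model predicting a negative depth), and summarises the N
#' bootstrap read-depth ratios of every callable cell
#' (\code{\link{summarizeRatios}}).  The whole procedure is driven by
#' \code{config@rngSeed} and is bit-reproducible.
#'
#' @param pd a \linkS4class{PanelDepth}, chromosome-X normalized and
#'   restricted to QC-passing samples.
#' @param config a \linkS4class{PanelConfig}.
#' @return A \linkS4class{CnvFit}.
#' @export
fitProbeModels <- function(pd, config = panelConfig()) {
  d <- depthValues(pd)
  K <- ncol(d); Tn <- nrow(d); N <- config@nBootstrap
  if (K < config@minSamples)
    qcError("%d samples provided but %d required to fit regression models",
            K, config@minSamples)
  med <- sampleMedians(pd)
  pools <- probePools(pd)

  slopes <- matrix(NA_real_, Tn, N)
  intercepts <- matrix(NA_real_, Tn, N)
  r2 <- matrix(NA_real_, Tn, N)
  dn <- list(rownames(d), colnames(d))
  faulty <- matrix(FALSE, Tn, K, dimnames = dn)
  medianRatio <- ciLo <- ciHi <- pDup <- pDel <-
    matrix(NA_real_, Tn, K, dimnames = dn)
  status <- matrix(NA_character_, Tn, K, dimnames = dn)

  withLocalSeed(config@rngSeed, {
    for (t in seq_len(Tn)) {
      m <- med[pools[t], ]
      y <- d[t, ]
      fit <- bootFitProbe(m, y, N)
      slopes[t, ] <- fit$slopes
      intercepts[t, ] <- fit$intercepts
      r2[t, ] <- fit$r2
      ok <- !is.na(fit$slopes)
      if (!any(ok)) next
      # predictions of every bootstrap model at every sample's median
      pred <- outer(fit$slopes[ok], m) + fit$intercepts[ok]
      faulty[t, ] <- apply(pred < 0, 2, any)
      for (k in seq_len(K)) {
        if (faulty[t, k]) next
        s <- summarizeRatios(y[k] / pred[, k], config)
        medianRatio[t, k] <- s$median; ciLo[t, k] <- s$ciLo
        ciHi[t, k] <- s$ciHi; pDup[t, k] <- s$pDup; pDel[t, k] <- s$pDel
        status[t, k] <- s$status
      }
    }
  })

  meanR2 <- rowMeans(r2, na.rm = TRUE)
  meanR2[is.nan(meanR2)] <- NA_real_
  anyNegative <- apply(slopes, 1, function(s) anyNA(s) || any(s < 0))
  quality <- ifelse(anyNegative, "faulty_probe",
                    ifelse(meanR2 < config@r2ProbeMin, "low_r2", "ok"))
  rownames(slopes) <- rownames(intercepts) <- rownames(r2) <- rownames(d)
  names(meanR2) <- names(quality) <- rownames(d)

  new("CnvFit", depth = pd, config = config,
      slopes = slopes, intercepts = intercepts, r2 = r2,
      meanR2 = meanR2, quality = quality, faultySamples = faulty,
      medianRatio = medianRatio, ciLo = ciLo, ciHi = ciHi,
      pDup = pDup, pDel = pDel, status = status)
}

#' Accessors for fitted ratio summaries
#'
#' Probe-by-sample matrices extracted from a \linkS4class{CnvFit}:
#' \code{ratioMedians} the median bootstrap ratio, \code{ratioCI} the
#' 2.5/97.5 percentile bounds (a list of two matrices), \code{probeCalls}
#' the per-cell status ("duplication"/"neutral"/"deletion", NA where the
#' cell is uncallable), \code{probeEvidence} the p_dup/p_del fractions,
#' \code{faultyCells} the faulty (probe, sample) mask, \code{probeMeanR2}
#' the per-probe mean bootstrap R-squared, and \code{probeFlags} the
#' per-probe quality flag.
#'
#' @param fit a \linkS4class{CnvFit}.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
ratioMedians <- function(fit) fit@medianRatio

#' @rdname fit-accessors
#' @export
ratioCI <- function(fit) list(lower = fit@ciLo, upper = fit@ciHi)

#' @rdname fit-accessors
#' @export
probeCalls <- function(fit) fit@status

#' @rdname fit-accessors
#' @export
probeEvidence <- function(fit) list(pDup = fit@pDup, pDel = fit@pDel)

#' @rdname fit-accessors
#' @export
faultyCells <- function(fit) fit@faultySamples

#' @rdname fit-accessors
#' @export
probeMeanR2 <- function(fit) fit@meanR2

#' @rdname fit-accessors
#' @export
probeFlags <- function(fit) fit@quality

# probes usable for calling: quality ok; cells additionally require a
# non-faulty, summarised ratio
callableProbes <- function(fit) fit@quality == "ok"

#' Write per-probe model and per-cell ratio summary tables
#'
#' \code{writeModelSummary} emits one row per probe (mean slope, mean
#' R-squared, quality flag, faulty samples); \code{writeRatioTable} one row
#' per callable (probe, sample) cell (median ratio, CI bounds, evidence
#' fractions, status).
#'
#' @param fit a \linkS4class{CnvFit}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeModelSummary <- function(fit, path) {
  df <- data.frame(
    probe_id = rownames(fit@slopes),
    mean_slope = rowMeans(fit@slopes, na.rm = TRUE),
    mean_r2 = fit@meanR2,
    quality = fit@quality,
    faulty_samples = apply(fit@faultySamples, 1, function(f)
      paste(colnames(fit@faultySamples)[f], collapse = ",")),
    row.names = NULL, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeModelSummary
#' @export
writeRatioTable <- function(fit, path) {
  keep <- which(!is.na(fit@medianRatio), arr.ind = TRUE)
  df <- data.frame(
    probe_id = rownames(fit@medianRatio)[keep[, 1]],
    sample_id = colnames(fit@medianRatio)[keep[, 2]],
    median_ratio = fit@medianRatio[keep],
    ci_lower = fit@ciLo[keep], ci_upper = fit@ciHi[keep],
    p_dup = fit@pDup[keep], p_del = fit@pDel[keep],
    status = fit@status[keep],
    row.names = NULL, stringsAsFactors = FALSE)
  df <- df[order(df$probe_id, df$sample_id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
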