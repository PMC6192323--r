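#' Inter-sample depth correlations for sample QC
#'
#' For every sample, the Pearson correlation of its probe-depth vector with
#' each other sample's, summarised by the "top quadrant" (by default the
#' 75th percentile) of those coefficients.  A sample with a constant depth
#' vector has no defined correlation and automatically fails with reason
#' "degenerate depth profile".
#'
#' @param pd a \linkS4class{PanelDepth} (at least two samples).
#' @param topQuadrant how to summarise the upper quartile of a sample's
#'   correlation coefficients: the 75th percentile (default), or the mean or
#'   max of the top quartile.
#' @param perPool compute correlations within each pool and average them,
#'   instead of panel-wide (default panel-wide).
#' @return A data.frame with one row per sample: \code{sample_id},
#'   \code{mean_depth}, \code{top_quadrant_corr}, \code{degenerate}; the
#'   full correlation matrix is attached as attribute \code{"corr"}.
#' @export
sampleCorrelations <- function(pd, topQuadrant = c("p75", "mean_top", "max_top"),
                               perPool = FALSE) {
  topQuadrant <- match.arg(topQuadrant)
  d <- depthValues(pd)
  if (ncol(d) < 2L) validationError("sample QC needs at least two samples")
  corMat <- if (perPool) {
    pools <- probePools(pd)
    mats <- lapply(unique(pools), function(p)
      suppressWarnings(cor(d[pools == p, , drop = FALSE])))
    Reduce(`+`, mats) / length(mats)
  } else suppressWarnings(cor(d))
  diag(corMat) <- NA
  summarise <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    switch(topQuadrant,
      p75 = unname(quantile(v, 0.75)),
      mean_top = mean(v[v >= quantile(v, 0.75)]),
      max_top = max(v))
  }
  degenerate <- apply(d, 2, function(x) sd(x) == 0 || !all(is.finite(x)))
  tqc <- apply(corMat, 2, summarise)
  tqc[degenerate] <- NA_real_
  rep <- data.frame(
    sample_id = colnames(d),
    mean_depth = colMeans(d),
    top_quadrant_corr = tqc,
    degenerate = degenerate,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(rep, "corr") <- corMat
  rep
}

#' Partition samples into QC pass/fail sets
#'
#' A sample fails when its top-quadrant correlation is below
#' \code{config@corrMin} (strictly below the published 0.7 default) or its
#' depth profile is degenerate.  Filtering is single-pass: correlations are
#' not recomputed after exclusions.  Mean target depth below the
#' recommendation for the capture mode (100x hybridization, 150x PCR) only
#' raises a warning.  Fewer than \code{config@minSamples} passing samples is
#' a hard error, since the regression models are meaningless below that.
#'
#' @param reports output of \code{\link{sampleCorrelations}}.
#' @param config a \linkS4class{PanelConfig}.
#' @param mode capture mode, used only for the depth recommendation warning.
#' @return A list with \code{pass} and \code{fail} character vectors and the
#'   annotated \code{reports} data.frame (columns \code{pass},
#'   \code{reasons} added).
#' @export
filterSamples <- function(reports, config = panelConfig(),
                          mode = c("hybridization", "pcr")) {
  mode <- match.arg(mode)
  reasons <- vector("list", nrow(reports))
  fail <- logical(nrow(reports))
  for (i in seq_len(nrow(reports))) {
    r <- character()
    if (reports$degenerate[i]) r <- c(r, "degenerate depth profile")
    else if (is.na(reports$top_quadrant_corr[i]))
      r <- c(r, "correlations undefined")
    else if (reports$top_quadrant_corr[i] < config@corrMin)
      r <- c(r, sprintf("top-quadrant correlation %.3f < %.2f",
                        reports$top_quadrant_corr[i], config@corrMin))
    fail[i] <- length(r) > 0L
    reasons[[i]] <- r
  }
  minDepth <- if (mode == "hybridization") 100 else 150
  low <- reports$mean_depth < minDepth
  if (any(low))
    warning(sprintf("mean target depth below the recommended %dx for %s: %s",
                    minDepth, mode,
                    paste(reports$sample_id[low], collapse = ", ")))
  reports$pass <- !fail
  reports$reasons <- vapply(reasons, paste, character(1), collapse = "; ")
  pass <- reports$sample_id[!fail]
  if (length(pass) < config@minSamples)
    qcError("only %d sample(s) pass QC but %d are required; failing: %s",
            length(pass), config@minSamples,
            paste(reports$sample_id[fail], collapse = ", "))
  list(pass = pass, fail = reports$sample_id[fail], reports = reports)
}

#' Write the per-sample QC report TSV
#'
#' @param reports annotated report data.frame from
#'   \code{\link{filterSamples}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeQcReport <- function(reports, path) {
  write.table(reports, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
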