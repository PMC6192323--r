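# ---- circular binary segmentation -----------------------------------------
#
# The change-point statistic follows Olshen-style CBS: for an ordered
# profile z (log2 ratios) every contiguous arc [i..j] with 1 <= length <= L-1
# is compared against its complement with a two-sample t statistic using the
# pooled variance; because the complement of a wrapped (circular) arc is a
# linear arc, scanning linear arcs covers every circular partition.
# Significance is assessed by permutation: the profile values are permuted
# (sample(z), cbsPerms times, RNG seeded from the configuration so results
# are reproducible) and the observed maximal arc statistic is compared with
# the permutation maxima.  Counting uses a small relative tolerance so that
# permutations realising the same partition as the observed optimum (equal
# statistic up to floating-point summation order) are always counted.

# all candidate arcs for a profile of length L
arcIndex <- function(L) {
  i <- rep(seq_len(L), times = L - seq_len(L) + 1L)
  j <- unlist(lapply(seq_len(L), function(a) seq(a, L)))
  keep <- (j - i + 1L) < L
  cbind(i = i[keep], j = j[keep])
}

# max two-sample arc statistic; zmat has one profile per row (permutations
# are evaluated in batch).  Returns the per-row maximum and, for the first
# row, the argmax arc (first arc in (i, j) scan order on strict improvement).
maxArcStat <- function(zmat, arcs = arcIndex(ncol(zmat))) {
  L <- ncol(zmat)
  B <- nrow(zmat)
  nin <- arcs[, "j"] - arcs[, "i"] + 1L
  nout <- L - nin
  # arc sums via indicator matrix multiply: (B x L) %*% (L x A)
  ind <- matrix(0, L, nrow(arcs))
  for (a in seq_len(nrow(arcs))) ind[arcs[a, "i"]:arcs[a, "j"], a] <- 1
  sumIn <- zmat %*% ind
  ssIn <- (zmat * zmat) %*% ind
  tot <- rowSums(zmat)
  totSS <- rowSums(zmat * zmat)
  sumOut <- tot - sumIn
  ssOut <- totSS - ssIn
  meanIn <- sweep(sumIn, 2, nin, "/")
  meanOut <- sweep(sumOut, 2, nout, "/")
  if (L > 2) {
    pooled <- (pmax(ssIn - sweep(sumIn^2, 2, nin, "/"), 0) +
               pmax(ssOut - sweep(sumOut^2, 2, nout, "/"), 0)) / (L - 2)
  } else pooled <- matrix(0, B, nrow(arcs))
  se <- sqrt(pooled) * rep(sqrt(1 / nin + 1 / nout), each = B)
  diff <- abs(meanIn - meanOut)
  stat <- ifelse(se > 0, diff / se, ifelse(diff > 0, Inf, 0))
  best <- apply(stat, 1, max)
  firstArg <- which(stat[1, ] == best[1])[1]
  list(max = best, arc = arcs[firstArg, ])
}

# permutation p-value for splitting one segment.  seed is fixed per
# configuration: every test call draws its permutations from the same
# stream, which keeps the procedure deterministic and call-order free.
segSplitTest <- function(z, config) {
  L <- length(z)
  arcs <- arcIndex(L)
  obs <- maxArcStat(matrix(z, 1), arcs)
  if (obs$max[1] <= 0) return(list(p = 1, arc = obs$arc))
  B <- config@cbsPerms
  perms <- withLocalSeed(config@rngSeed, {
    t(vapply(seq_len(B), function(b) sample(z), numeric(L)))
  })
  permMax <- maxArcStat(perms, arcs)$max
  tol <- if (is.finite(obs$max[1])) obs$max[1] * 1e-9 + 1e-12 else 0
  p <- (1 + sum(permMax >= obs$max[1] - tol)) / (B + 1)
  list(p = p, arc = obs$arc)
}

#' Circular binary segmentation of a ratio profile
#'
#' Recursively partitions an ordered profile of (capped) read-depth ratios
#' into constant-mean segments.  At each step the arc maximising the
#' two-sample t statistic on log2 ratios is tested by permutation
#' (\code{config@cbsPerms} permutations, accepted when p <
#' \code{config@cbsAlpha}); accepted splits recurse into the resulting
#' sub-segments.
#'
#' @param values numeric vector of capped median read-depth ratios, in
#'   genomic order (see \code{\link{capRatios}}).
#' @param config a \linkS4class{PanelConfig}.
#' @return A data.frame with one row per segment: \code{start}, \code{end}
#'   (indices into \code{values}), \code{n}, \code{mean_ratio} (arithmetic
#'   mean of the ratios in the segment).
#' @export
cbsSegment <- function(values, config = panelConfig()) {
  if (!length(values)) validationError("cannot segment an empty profile")
  if (any(!is.finite(values) | values <= 0))
    validationError("profile values must be positive and finite")
  z <- log2(values)
  bounds <- segmentRecurse(z, 1L, length(z), config)
  data.frame(
    start = vapply(bounds, `[`, integer(1), 1),
    end = vapply(bounds, `[`, integer(1), 2),
    n = vapply(bounds, function(b) b[2] - b[1] + 1L, integer(1)),
    mean_ratio = vapply(bounds, function(b) mean(values[b[1]:b[2]]),
                        numeric(1)))
}

segmentRecurse <- function(z, from, to, config) {
  L <- to - from + 1L
  if (L < 2L) return(list(c(from, to)))
  test <- segSplitTest(z[from:to], config)
  if (test$p >= config@cbsAlpha) return(list(c(from, to)))
  i <- from + test$arc[["i"]] - 1L
  j <- from + test$arc[["j"]] - 1L
  out <- list()
  if (i > from) out <- c(out, segmentRecurse(z, from, i - 1L, config))
  out <- c(out, segmentRecurse(z, i, j, config))
  if (j < to) out <- c(out, segmentRecurse(z, j + 1L, to, config))
  out
}

#' Cap ratios entering a segmentation profile
#'
#' Median bootstrap ratios above \code{cap} (default 16) enter the per-gene
#' profile as exactly \code{cap}, bounding the influence of extreme
#' amplifications.
#'
#' @param values numeric median read-depth ratios.
#' @param cap upper limit (default 16).
#' @return The capped values.
#' @export
capRatios <- function(values, cap = 16) pmin(values, cap)

#' Classify segments by mean ratio and merge same-status neighbours
#'
#' A segment is a deletion when its mean ratio is strictly below
#' \code{thDel}, a duplication when strictly above \code{thDup}, otherwise
#' neutral.  Adjacent segments of equal non-neutral status are merged
#' iteratively (probe-count-weighted mean) until a fixpoint; merging never
#' bridges a neutral segment.
#'
#' @param segments data.frame from \code{\link{cbsSegment}}.
#' @param config a \linkS4class{PanelConfig}.
#' @return The merged data.frame with an added \code{status} column.
#' @export
mergeSegments <- function(segments, config = panelConfig()) {
  segStatus <- function(m)
    ifelse(m < config@thDel, "deletion",
           ifelse(m > config@thDup, "duplication", "neutral"))
  segments$status <- segStatus(segments$mean_ratio)
  repeat {
    if (nrow(segments) < 2L) break
    same <- segments$status[-1] == segments$status[-nrow(segments)] &
      segments$status[-1] != "neutral"
    hit <- which(same)
    if (!length(hit)) break
    a <- hit[1]; b <- a + 1L
    na <- segments$n[a]; nb <- segments$n[b]
    segments$end[a] <- segments$end[b]
    segments$mean_ratio[a] <-
      (segments$mean_ratio[a] * na + segments$mean_ratio[b] * nb) / (na + nb)
    segments$n[a] <- na + nb
    segments <- segments[-b, , drop = FALSE]
    rownames(segments) <- NULL
  }
  segments
}

#' Rescue short runs of strong probe-level signals
#'
#' Maximal runs of two or more consecutive probes sharing the same
#' non-neutral probe-level status (evidence fraction above
#' \code{config@rescueProb}) are emitted as candidates even when
#' segmentation missed them; runs overlapping an existing candidate of the
#' same type are skipped.  Consecutiveness is evaluated over the unmasked
#' probe sequence.
#'
#' @param statuses character vector of per-probe statuses
#'   ("duplication"/"neutral"/"deletion") in profile order.
#' @param pDup,pDel numeric vectors of evidence fractions, same order.
#' @param existing data.frame of already-emitted candidates for this
#'   profile, with columns \code{start}, \code{end}, \code{status} (indices
#'   into the same profile); may be empty.
#' @param config a \linkS4class{PanelConfig}.
#' @return data.frame of rescued runs: \code{start}, \code{end}, \code{n},
#'   \code{status}.
#' @export
rescueRuns <- function(statuses, pDup, pDel, existing = NULL,
                       config = panelConfig()) {
  strong <- ifelse(is.na(statuses), "neutral",
    ifelse(statuses == "duplication" & pDup > config@rescueProb, "duplication",
    ifelse(statuses == "deletion" & pDel > config@rescueProb, "deletion",
           "neutral")))
  r <- rle(strong)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "neutral" & r$lengths >= 2L
  runs <- data.frame(start = starts[keep], end = ends[keep],
                     n = r$lengths[keep], status = r$values[keep],
                     stringsAsFactors = FALSE)
  if (!is.null(existing) && nrow(existing) && nrow(runs)) {
    clash <- vapply(seq_len(nrow(runs)), function(i) {
      any(existing$status == runs$status[i] &
          existing$start <= runs$end[i] & existing$end >= runs$start[i])
    }, logical(1))
    runs <- runs[!clash, , drop = FALSE]
  }
  rownames(runs) <- NULL
  runs
}

#' Estimate the copy number of a candidate
#'
#' Per-probe copy number is the median read-depth ratio times the neutral
#' copy count at the probe (2 on autosomes; on chromosome X, 1 for males and
#' 2 for females, matching the gender normalization convention); the
#' candidate estimate is the mean over member probes.
#'
#' @param ratios numeric median ratios of the member probes (uncapped).
#' @param multipliers numeric neutral copy count per probe (default 2).
#' @return A list with \code{raw} (mean) and \code{rounded} estimates.
#' @export
estimateCopyNumber <- function(ratios, multipliers = 2) {
  cn <- ratios * multipliers
  list(raw = mean(cn), rounded = round(mean(cn)))
}

# neutral copy count per probe for one sample
copyMultipliers <- function(chrom, gender) {
  ifelse(isChrX(chrom), ifelse(identical(gender, "male"), 1, 2), 2)
}

#' Call CNV candidates from a fitted cohort
#'
#' Runs per-(gene, sample) segmentation of the capped median-ratio profiles,
#' classifies and merges segments, applies the consecutive-run rescue rule,
#' estimates copy numbers, annotates genomic spans from the member probes,
#' and scores every candidate (\code{\link{scoreCandidates}}).  Probes
#' flagged faulty or low-R2, and faulty (probe, sample) cells, are excluded
#' from profiles; probes without a gene label are grouped per chromosome.
#'
#' @param fit a \linkS4class{CnvFit}.
#' @param config the \linkS4class{PanelConfig} (defaults to the one stored
#'   in the fit).
#' @return A data.frame of scored candidates ordered by (sample, chrom,
#'   start); zero rows when nothing is called.
#' @export
callCnvs <- function(fit, config = fit@config) {
  pd <- fit@depth
  rr <- SummarizedExperiment::rowRanges(pd)
  mc <- S4Vectors::mcols(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  gene <- as.character(mc$gene)
  gene[is.na(gene) | gene == ""] <- paste0("unassigned_",
                                           chrom[is.na(gene) | gene == ""])
  ord <- order(factor(chrom, unique(chrom)), GenomicRanges::start(rr))
  callable <- callableProbes(fit)

  out <- list()
  for (s in colnames(pd)) {
    gender <- SummarizedExperiment::colData(pd)[s, "gender"]
    for (g in unique(gene[ord])) {
      probes <- ord[gene[ord] == g]
      usable <- probes[callable[probes] &
                       !fit@faultySamples[probes, s] &
                       !is.na(fit@medianRatio[probes, s])]
      if (!length(usable)) next
      ratios <- fit@medianRatio[usable, s]
      profile <- capRatios(ratios, config@profileCap)
      segs <- mergeSegments(cbsSegment(profile, config), config)
      cands <- segs[segs$status != "neutral", , drop = FALSE]
      cands$origin <- rep("cbs", nrow(cands))
      rescued <- rescueRuns(fit@status[usable, s],
                            fit@pDup[usable, s], fit@pDel[usable, s],
                            existing = cands, config = config)
      if (nrow(rescued)) {
        rescued$mean_ratio <- vapply(seq_len(nrow(rescued)), function(i)
          mean(profile[rescued$start[i]:rescued$end[i]]), numeric(1))
        rescued$origin <- "rescue"
        cands <- rbind(cands[, c("start", "end", "n", "mean_ratio",
                                 "status", "origin")],
                       rescued[, c("start", "end", "n", "mean_ratio",
                                   "status", "origin")])
      }
      if (!nrow(cands)) next
      rows <- lapply(seq_len(nrow(cands)), function(i) {
        members <- usable[cands$start[i]:cands$end[i]]
        mult <- copyMultipliers(chrom[members], gender)
        cn <- estimateCopyNumber(fit@medianRatio[members, s], mult)
        log2r <- log2(fit@medianRatio[members, s])
        ciLen <- log2(fit@ciHi[members, s]) - log2(fit@ciLo[members, s])
        data.frame(
          sample_id = s, gene = g, cnv_type = cands$status[i],
          chrom = chrom[members[1]],
          start = min(GenomicRanges::start(rr)[members]) - 1L,
          end = max(GenomicRanges::end(rr)[members]),
          first_probe = mc$probe_id[members[1]],
          last_probe = mc$probe_id[members[length(members)]],
          n_probes = length(members),
          copy_number_raw = cn$raw, copy_number = cn$rounded,
          origin = cands$origin[i],
          mean_ratio = mean(fit@medianRatio[members, s]),
          mean_log2_ratio = mean(log2r),
          sd_log2_ratio = popSD(log2r),
          mean_log2_ci = mean(ciLen),
          mean_r2 = mean(fit@meanR2[members]),
          stringsAsFactors = FALSE)
      })
      out <- c(out, rows)
    }
  }
  if (!length(out)) {
    res <- emptyCandidates()
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$sample_id, factor(res$chrom, unique(chrom)),
                     res$start), ]
    rownames(res) <- NULL
  }
  scoreCandidates(res, config)
}

emptyCandidates <- function() {
  data.frame(sample_id = character(), gene = character(),
             cnv_type = character(), chrom = character(),
             start = integer(), end = integer(),
             first_probe = character(), last_probe = character(),
             n_probes = integer(), copy_number_raw = numeric(),
             copy_number = numeric(), origin = character(),
             mean_ratio = numeric(), mean_log2_ratio = numeric(),
             sd_log2_ratio = numeric(), mean_log2_ci = numeric(),
             mean_r2 = numeric(), stringsAsFactors = FALSE)
}

#' Write the candidate table, optionally as BED
#'
#' @param candidates scored candidate data.frame from \code{\link{callCnvs}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCandidates <- function(candidates, path) {
  write.table(candidates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCandidates
#' @export
candidatesToBed <- function(candidates, path) {
  bed <- data.frame(candidates$chrom, candidates$start, candidates$end,
                    paste(candidates$gene, candidates$cnv_type,
                          candidates$score, sep = ":"))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
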