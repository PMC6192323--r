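# Independent oracles used to cross-check the package implementations.
# They deliberately use naive formulations (explicit loops, lm.fit, direct
# per-base counting) rather than the package's vectorised code paths.

# --- bootstrap regression oracle -------------------------------------------
# Reproduces the documented resampling convention (index matrix drawn as
# matrix(sample.int(K, N*K, TRUE), N, K) from the configured seed, probes in
# row order) but fits every resample with lm.fit and computes R-squared from
# residual sums of squares.
oracleBootstrap <- function(pd, config) {
  d <- SummarizedExperiment::assay(pd, "depth")
  med <- apply(d, 2, median)
  N <- config@nBootstrap
  K <- ncol(d)
  out <- vector("list", nrow(d))
  set.seed(config@rngSeed)
  for (t in seq_len(nrow(d))) {
    idx <- matrix(sample.int(K, N * K, replace = TRUE), N, K)
    slopes <- intercepts <- r2 <- numeric(N)
    for (n in seq_len(N)) {
      x <- med[idx[n, ]]
      y <- d[t, idx[n, ]]
      fit <- lm.fit(cbind(1, x), y)
      slopes[n] <- fit$coefficients[2]
      intercepts[n] <- fit$coefficients[1]
      sst <- sum((y - mean(y))^2)
      r2[n] <- if (sst <= 0) 1 else 1 - sum(fit$residuals^2) / sst
    }
    # ratios for every sample, as y_obs over each model's prediction
    ratios <- sapply(seq_len(K), function(k)
      d[t, k] / (slopes * med[k] + intercepts))
    out[[t]] <- list(slopes = slopes, intercepts = intercepts, r2 = r2,
                     ratios = ratios)
  }
  out
}

# --- segmentation oracle ----------------------------------------------------
# Exhaustive maximal-statistic search: every arc is evaluated with plain
# mean()/sum() arithmetic; the permutation acceptance test follows the same
# published convention (seeded sample(), greater-or-equal count with the
# same relative tolerance) so that agreement tests the statistic and the
# recursion, not the random stream.
oracleArcStat <- function(z, i, j) {
  inside <- z[i:j]
  outside <- z[-(i:j)]
  d <- abs(mean(inside) - mean(outside))
  L <- length(z)
  if (L > 2) {
    pooled <- (sum((inside - mean(inside))^2) +
               sum((outside - mean(outside))^2)) / (L - 2)
  } else pooled <- 0
  se <- sqrt(pooled) * sqrt(1 / length(inside) + 1 / length(outside))
  if (se > 0) d / se else if (d > 0) Inf else 0
}

oracleMaxArc <- function(z) {
  L <- length(z)
  best <- -1; bi <- 1L; bj <- 1L
  for (i in seq_len(L)) {
    for (j in i:L) {
      if (j - i + 1L >= L) next
      s <- oracleArcStat(z, i, j)
      if (s > best) { best <- s; bi <- i; bj <- j }
    }
  }
  list(max = best, i = bi, j = bj)
}

oracleSegment <- function(values, config) {
  z <- log2(values)
  rec <- function(from, to) {
    L <- to - from + 1L
    if (L < 2L) return(list(c(from, to)))
    sub <- z[from:to]
    obs <- oracleMaxArc(sub)
    if (obs$max <= 0) return(list(c(from, to)))
    set.seed(config@rngSeed)
    hits <- 0L
    tol <- if (is.finite(obs$max)) obs$max * 1e-9 + 1e-12 else 0
    for (b in seq_len(config@cbsPerms)) {
      perm <- sample(sub)
      if (oracleMaxArc(perm)$max >= obs$max - tol) hits <- hits + 1L
    }
    p <- (1 + hits) / (config@cbsPerms + 1)
    if (p >= config@cbsAlpha) return(list(c(from, to)))
    i <- from + obs$i - 1L
    j <- from + obs$j - 1L
    out <- list()
    if (i > from) out <- c(out, rec(from, i - 1L))
    out <- c(out, rec(i, j))
    if (j < to) out <- c(out, rec(j + 1L, to))
    out
  }
  b <- rec(1L, length(z))
  data.frame(start = vapply(b, `[`, integer(1), 1),
             end = vapply(b, `[`, integer(1), 2))
}

# --- per-base coverage oracle ----------------------------------------------
# mean coverage of an interval computed by counting overlapping reads at
# every single base
oracleMeanCoverage <- function(reads, chrom, start, end) {
  bases <- start:end
  cov <- vapply(bases, function(b)
    sum(reads$chrom == chrom & reads$pos <= b & reads$pos + reads$len - 1 >= b),
    numeric(1))
  mean(cov)
}
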