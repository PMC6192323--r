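#' @importFrom ggplot2 .data
NULL

# assemble the per-probe plotting table for one sample: ordinal position,
# log2 median ratio, CI whiskers, evidence colour value 1 - max(pDup, pDel),
# and a glyph class combining pool with probe quality
plotTable <- function(fit, sample, genes = NULL) {
  pd <- fit@depth
  if (!sample %in% colnames(pd))
    validationError("unknown sample '%s'", sample)
  rr <- SummarizedExperiment::rowRanges(pd)
  mc <- S4Vectors::mcols(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  ord <- order(factor(chrom, unique(chrom)), GenomicRanges::start(rr))
  df <- data.frame(
    probe_id = mc$probe_id[ord],
    gene = as.character(mc$gene)[ord],
    exon = as.character(mc$exon)[ord],
    chrom = chrom[ord],
    start = GenomicRanges::start(rr)[ord] - 1L,
    end = GenomicRanges::end(rr)[ord],
    pool = as.character(mc$pool)[ord],
    quality = fit@quality[ord],
    ratio = fit@medianRatio[ord, sample],
    ciLo = fit@ciLo[ord, sample],
    ciHi = fit@ciHi[ord, sample],
    pDup = fit@pDup[ord, sample],
    pDel = fit@pDel[ord, sample],
    faulty_cell = fit@faultySamples[ord, sample],
    stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    if (!all(genes %in% df$gene))
      validationError("unknown gene(s): %s",
                      paste(setdiff(genes, df$gene), collapse = ", "))
    df <- df[df$gene %in% genes, , drop = FALSE]
  }
  if (!nrow(df)) validationError("no probes to plot")
  df$index <- seq_len(nrow(df))
  df$pvalue <- 1 - pmax(df$pDup, df$pDel)
  df$pvalue[is.na(df$pvalue)] <- 1
  df$glyph <- df$pool
  df$glyph[df$quality != "ok"] <- df$quality[df$quality != "ok"]
  df$glyph[df$quality == "ok" & df$faulty_cell] <- "faulty_cell"
  df
}

ratioPlotBase <- function(df, config, title) {
  df$log2ratio <- log2(df$ratio)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$log2ratio)) +
    ggplot2::geom_hline(yintercept = log2(config@thDup),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_hline(yintercept = log2(config@thDel),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = log2(.data$ciLo), ymax = log2(.data$ciHi)),
      width = 0, colour = "grey65", na.rm = TRUE) +
    ggplot2::geom_point(
      ggplot2::aes(fill = .data$pvalue, shape = .data$glyph),
      size = 2.4, colour = "grey25", na.rm = TRUE) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "red",
                                 high = "white", name = "1 - p.dup/p.del") +
    ggplot2::scale_shape_manual(
      values = setNames(c(21, 22, 23, 24, 25, 4, 8, 3)[
        seq_along(unique(df$glyph))], sort(unique(df$glyph))),
      name = "pool / quality") +
    ggplot2::labs(title = title, x = "probe (panel order)",
                  y = "log2 read-depth ratio") +
    ggplot2::theme_bw()
}

#' Whole-panel ratio plot for one sample
#'
#' All probes of the panel in genomic order at equal spacing, log2 median
#' ratios with 95 percent CI whiskers, dotted duplication/deletion threshold
#' lines, point colour encoding 1 - max(p.dup, p.del) on a red-white
#' gradient and point shape encoding pool / faulty / low-quality class.
#'
#' @param fit a \linkS4class{CnvFit}.
#' @param sample sample identifier.
#' @param config a \linkS4class{PanelConfig} (defaults to the fit's).
#' @return A ggplot object.
#' @export
plotWholePanel <- function(fit, sample, config = fit@config) {
  df <- plotTable(fit, sample)
  breaks <- df$index[!duplicated(df$gene)]
  p <- ratioPlotBase(df, config, sprintf("%s - whole panel", sample))
  p + ggplot2::scale_x_continuous(
    breaks = breaks[seq(1, length(breaks), length.out = min(25, length(breaks)))])
}

#' Gene-centric ratio plot
#'
#' The gene's probes with CI whiskers, pool/quality glyphs and the evidence
#' gradient; candidate spans within the gene are shaded and labelled with
#' their confidence score.
#'
#' @param fit a \linkS4class{CnvFit}.
#' @param sample sample identifier.
#' @param gene gene symbol (must exist in the panel).
#' @param candidates optional scored candidate data.frame; rows for this
#'   sample and gene are drawn as shaded spans labelled with the score.
#' @param config a \linkS4class{PanelConfig} (defaults to the fit's).
#' @return A ggplot object.
#' @export
plotGene <- function(fit, sample, gene, candidates = NULL,
                     config = fit@config) {
  df <- plotTable(fit, sample, genes = gene)
  p <- ratioPlotBase(df, config, sprintf("%s - %s", sample, gene)) +
    ggplot2::scale_x_continuous(breaks = df$index,
                                labels = ifelse(is.na(df$exon),
                                                df$probe_id, df$exon))
  if (!is.null(candidates) && nrow(candidates)) {
    cc <- candidates[candidates$sample_id == sample &
                     candidates$gene == gene, , drop = FALSE]
    if (nrow(cc)) {
      spans <- do.call(rbind, lapply(seq_len(nrow(cc)), function(i) {
        inside <- df$index[df$start >= cc$start[i] & df$end <= cc$end[i]]
        data.frame(xmin = min(inside) - 0.35, xmax = max(inside) + 0.35,
                   score = cc$score[i], type = cc$cnv_type[i])
      }))
      p <- p +
        ggplot2::geom_rect(data = spans, inherit.aes = FALSE,
          ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                       ymin = -Inf, ymax = Inf),
          fill = ifelse(spans$type == "deletion", "steelblue", "orange"),
          alpha = 0.15) +
        ggplot2::geom_text(data = spans, inherit.aes = FALSE,
          ggplot2::aes(x = (.data$xmin + .data$xmax) / 2, y = Inf,
                       label = .data$score), vjust = 1.4, size = 3.2)
    }
  }
  p
}

#' Render plots for a cohort and write a manifest
#'
#' Writes one whole-panel plot per sample and one gene-centric plot per
#' (sample, gene with at least one candidate) — or all genes when
#' \code{genes = "all"} — in the requested formats, plus a manifest TSV
#' listing every file produced.
#'
#' @param fit a \linkS4class{CnvFit}.
#' @param candidates scored candidate data.frame.
#' @param dir output directory.
#' @param formats subset of c("pdf", "png").
#' @param genes "auto" (genes with candidates) or "all".
#' @param width,height device size in inches.
#' @return Invisibly, the manifest data.frame (also written to
#'   \code{dir/plots.tsv}).
#' @export
savePanelPlots <- function(fit, candidates, dir, formats = c("pdf", "png"),
                           genes = c("auto", "all"), width = 10, height = 4) {
  genes <- match.arg(genes)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  emit <- function(plot, base) {
    for (fmt in formats) {
      f <- file.path(dir, paste0(base, ".", fmt))
      suppressMessages(ggplot2::ggsave(f, plot, width = width,
                                       height = height, dpi = 96))
      rows[[length(rows) + 1L]] <<- data.frame(file = basename(f),
                                               stringsAsFactors = FALSE)
    }
  }
  for (s in colnames(fit@depth)) {
    emit(plotWholePanel(fit, s), sprintf("%s.whole_panel", s))
    gs <- if (genes == "all")
      unique(as.character(S4Vectors::mcols(
        SummarizedExperiment::rowRanges(fit@depth))$gene))
    else unique(candidates$gene[candidates$sample_id == s])
    for (g in gs)
      emit(plotGene(fit, s, g, candidates), sprintf("%s.gene.%s", s, g))
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(), stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "plots.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
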