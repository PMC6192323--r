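#' Score one CNV candidate on the five confidence criteria
#'
#' One point per satisfied criterion: (1) at least \code{probeCntMin}
#' supporting probes; (2) mean log2 median ratio strictly below
#' \code{log2DelMax} for deletions / strictly above \code{log2DupMin} for
#' duplications; (3) standard deviation of the log2 median ratios strictly
#' below \code{stdMax} (population formula, so a single probe scores 0 SD);
#' (4) mean log2 95 percent CI length strictly below \code{ciMax}; (5) mean
#' of the member probes' mean bootstrap R-squared at least
#' \code{r2ScoreMin}.
#'
#' @param nProbes number of member probes.
#' @param meanLog2Ratio mean of the log2 median ratios of member probes.
#' @param sdLog2Ratio their population standard deviation.
#' @param meanLog2CI mean log2-transformed 95 percent CI length
#'   (log2(upper) - log2(lower)).
#' @param meanR2 mean of the member probes' mean bootstrap R-squared.
#' @param type "deletion" or "duplication".
#' @param config a \linkS4class{PanelConfig}.
#' @return A list with logical \code{pass} (named, one per criterion) and
#'   integer \code{total} in 0..5.
#' @examples
#' scoreCandidate(3, -1.2, 0.2, 0.3, 0.9, "deletion")$total
#' @export
scoreCandidate <- function(nProbes, meanLog2Ratio, sdLog2Ratio, meanLog2CI,
                           meanR2, type = c("deletion", "duplication"),
                           config = panelConfig()) {
  type <- match.arg(type)
  pass <- c(
    ProbeCntInRegion = nProbes >= config@probeCntMin,
    AverageOfReadDepthRatios = if (type == "deletion")
      meanLog2Ratio < config@log2DelMax else meanLog2Ratio > config@log2DupMin,
    STDOfReadDepthRatios = sdLog2Ratio < config@stdMax,
    AverageOfCIs = meanLog2CI < config@ciMax,
    AverageOfR2vals = meanR2 >= config@r2ScoreMin)
  list(pass = pass, total = as.integer(sum(pass)))
}

#' Score a table of CNV candidates
#'
#' Applies \code{\link{scoreCandidate}} to every row of a candidate table
#' (as produced by \code{\link{callCnvs}}), appending one pass/fail column
#' per criterion and the total \code{score}.  All candidates are retained
#' whatever their score; consumers filter downstream.
#'
#' @param candidates candidate data.frame with columns \code{n_probes},
#'   \code{mean_log2_ratio}, \code{sd_log2_ratio}, \code{mean_log2_ci},
#'   \code{mean_r2}, \code{cnv_type}.
#' @param config a \linkS4class{PanelConfig}.
#' @return The data.frame with criterion columns and \code{score} appended.
#' @export
scoreCandidates <- function(candidates, config = panelConfig()) {
  crit <- c("ProbeCntInRegion", "AverageOfReadDepthRatios",
            "STDOfReadDepthRatios", "AverageOfCIs", "AverageOfR2vals")
  for (cn in crit) candidates[[cn]] <- logical(nrow(candidates))
  candidates$score <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    s <- scoreCandidate(candidates$n_probes[i],
                        candidates$mean_log2_ratio[i],
                        candidates$sd_log2_ratio[i],
                        candidates$mean_log2_ci[i],
                        candidates$mean_r2[i],
                        candidates$cnv_type[i], config)
    for (cn in crit) candidates[[cn]][i] <- s$pass[[cn]]
    candidates$score[i] <- s$total
  }
  candidates
}
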