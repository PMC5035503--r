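#' Predict at-risk animals before imputation
#'
#' Flags target animals expected to impute poorly, using only low-density
#' genotypes: for each target the average Mendelian-inconsistency count
#' over the k lowest-MI reference animals (AVTOP10, see [avTopMI()]) is
#' computed on the shared low-density SNPs, and animals whose value
#' strictly exceeds the threshold are flagged `at-risk`.  Default
#' thresholds follow published sheep-population practice — 400 for a
#' 5K-like panel, 3000 for a 50K-like panel — but are population- and
#' panel-dependent: [calibrateThreshold()] is the recommended path on new
#' data, and custom panels require an explicit threshold.
#'
#' @param lowDensity targets: [GenotypeData] at the low panel density.
#' @param reference [GenotypeData] of reference animals on the same frame
#'   (only the shared low-density SNPs are used).
#' @param panelLabel `"5K"`, `"50K"` or `"custom"`.
#' @param threshold MI threshold; defaults 400 (`"5K"`) / 3000 (`"50K"`),
#'   required for `"custom"`.
#' @param k reference animals averaged (default 10).
#' @return data.frame ("PredictionReport") with per-target `avTopMI`,
#'   `meanTop10G` (mean top-k genomic relationship to the reference, for
#'   comparison), `flag` (`"pass"`/`"at-risk"`); attributes `threshold`
#'   and `panel`.
#' @export
predictAtRisk <- function(lowDensity, reference,
                          panelLabel = c("5K", "50K", "custom"),
                          threshold = NULL, k = 10L) {
  panelLabel <- match.arg(panelLabel)
  stopifnot(is(lowDensity, "GenotypeData"), is(reference, "GenotypeData"))
  .assertSameFrame(dosages(lowDensity), dosages(reference))
  if (is.null(threshold)) {
    threshold <- switch(panelLabel, `5K` = 400, `50K` = 3000,
                        custom = stop("custom panels need an explicit threshold"))
  }
  targets <- animalIds(lowDensity)
  refIds <- animalIds(reference)
  combined <- GenotypeData(cbind(dosages(lowDensity), dosages(reference)),
                           markerMapFrame(lowDensity))
  av <- avTopMI(combined, targets, refIds, k = k)
  grm <- computeG(combined, alleleFrequencies(combined))
  topk <- topKRelationships(grm, refIds, targets, k = k)
  out <- data.frame(target = av$target, avTopMI = av$avTopMI,
                    meanTop10G = topk$summary$mean,
                    flag = ifelse(av$avTopMI > threshold, "at-risk", "pass"),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "panel") <- panelLabel
  out
}

#' Calibrate the at-risk MI threshold on achieved accuracies
#'
#' Given per-animal AVTOP10 values and achieved concordance rates, finds
#' the MI cut maximizing balanced accuracy for classifying animals with
#' CR below `targetCR`, and reports the Spearman rank correlation between
#' AVTOP10 and CR (expected negative: higher inconsistency, lower
#' accuracy).  Candidate cuts are midpoints between consecutive sorted
#' AVTOP10 values.
#'
#' @param avTop10 numeric per-animal AVTOP10 values.
#' @param achievedCR numeric per-animal CR in percent, aligned.
#' @param targetCR accuracy boundary in percent (default 80).
#' @return list with `threshold` (NA if degenerate), `balancedAccuracy`,
#'   `rankCorrelation`, `nBelow` and a `note` when degenerate.
#' @export
calibrateThreshold <- function(avTop10, achievedCR, targetCR = 80) {
  if (length(avTop10) != length(achievedCR))
    stop("avTop10 and achievedCR must be aligned")
  ok <- !is.na(avTop10) & !is.na(achievedCR)
  avTop10 <- avTop10[ok]; achievedCR <- achievedCR[ok]
  if (length(avTop10) < 20) stop("need at least 20 animals with both values")
  rho <- suppressWarnings(cor(avTop10, achievedCR, method = "spearman"))
  poor <- achievedCR < targetCR
  if (all(poor) || !any(poor))
    return(list(threshold = NA_real_, balancedAccuracy = NA_real_,
                rankCorrelation = rho, nBelow = sum(poor),
                note = "all animals on one side of targetCR"))
  s <- sort(unique(avTop10))
  cuts <- (head(s, -1) + tail(s, -1)) / 2
  ba <- vapply(cuts, function(t) {
    flag <- avTop10 > t
    sens <- sum(flag & poor) / sum(poor)
    spec <- sum(!flag & !poor) / sum(!poor)
    (sens + spec) / 2
  }, numeric(1))
  best <- which.max(ba)
  list(threshold = cuts[best], balancedAccuracy = ba[best],
       rankCorrelation = rho, nBelow = sum(poor), note = NULL)
}
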