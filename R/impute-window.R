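## Deterministic window-haplotype reference imputer.
##
## For each target animal and each sliding window on the high panel's SNP
## order, the reference animal minimizing the mean absolute dosage
## difference on co-observed low-panel SNPs in the window is selected
## (ties -> lowest animal id) and its dosages are copied into the target's
## missing entries.  Overlapping windows vote per entry; majority wins and
## remaining ties take the value proposed by the later window.  The
## procedure is fully deterministic; it is a self-contained stand-in for
## external population imputers, not a re-implementation of any of them.

.windowStarts <- function(n, window, overlap) {
  if (window <= 1) stop("window must be at least 2 SNPs")
  if (overlap < 0 || overlap >= window) stop("need window > overlap >= 0")
  if (n <= window) return(1L)
  stride <- window - overlap
  starts <- seq(1L, n - window + 1L, by = stride)
  if (tail(starts, 1L) + window - 1L < n) starts <- c(starts, n - window + 1L)
  starts
}

#' Window-haplotype reference imputation
#'
#' Fills the missing genotypes of low-density targets from a reference set
#' fully genotyped on the high panel, using deterministic best-matching
#' reference selection in overlapping sliding windows (see Details in the
#' package vignette).  Observed genotypes always pass through unchanged.
#'
#' @param masked targets: a [GenotypeData] on the full SNP frame, observed
#'   on the low panel, missing elsewhere.
#' @param reference a [GenotypeData] on the same frame, fully genotyped on
#'   the high panel.
#' @param panelLow,panelHigh [PanelDef]s (or SNP-id vectors); `panelLow`
#'   must be a subset of `panelHigh`.
#' @param window,overlap window length and overlap in high-panel SNPs;
#'   `window > overlap >= 0`, `window >= 2`.
#' @return An [ImputationResult]; every high-panel entry is filled.
#' @export
imputeWindowHaplotype <- function(masked, reference, panelLow, panelHigh,
                                  window = 200L, overlap = 150L) {
  stopifnot(is(masked, "GenotypeData"), is(reference, "GenotypeData"))
  .assertSameFrame(dosages(masked), dosages(reference))
  lowIds <- if (is(panelLow, "PanelDef")) panelLow@snps else panelLow
  highIds <- if (is(panelHigh, "PanelDef")) panelHigh@snps else panelHigh
  if (!all(lowIds %in% highIds)) stop("low panel must be nested in high panel")
  d <- dosages(masked)
  refAll <- dosages(reference)
  if (ncol(refAll) == 0) stop("empty reference set")
  refOrder <- sort(colnames(refAll))
  R <- refAll[, refOrder, drop = FALSE]
  hiIdx <- which(rownames(d) %in% highIds)
  if (anyNA(R[hiIdx, ])) stop("reference must be fully genotyped on the high panel")
  isLow <- rownames(d) %in% lowIds
  nT <- ncol(d); nH <- length(hiIdx)
  starts <- .windowStarts(nH, window, overlap)
  nWin <- length(starts)
  votes <- lapply(0:2, function(v) matrix(0L, nrow(d), nT))
  lastw <- lapply(0:2, function(v) matrix(0L, nrow(d), nT))
  for (w in seq_len(nWin)) {
    idx <- hiIdx[starts[w]:min(starts[w] + window - 1L, nH)]
    lowWin <- idx[isLow[idx]]
    if (length(lowWin)) {
      Tm <- t(d[lowWin, , drop = FALSE])              # targets x c
      Rm <- t(R[lowWin, , drop = FALSE])              # refs x c
      obs <- !is.na(Tm)
      M <- matrix(0, nT, ncol(R))
      for (v in 0:2) {
        Iv <- (obs & Tm == v) * 1
        M <- M + Iv %*% t(abs(Rm - v))
      }
      cnt <- rowSums(obs)
      M[cnt > 0, ] <- M[cnt > 0, , drop = FALSE] / cnt[cnt > 0]
      M[cnt == 0, ] <- 0    # no information: all tie -> first reference id
    } else {
      M <- matrix(0, nT, ncol(R))                     # all tie -> first id
    }
    choice <- max.col(-M, ties.method = "first")
    B <- R[idx, choice, drop = FALSE]                 # proposed dosages
    for (v in 0:2) {
      inc <- B == v
      votes[[v + 1]][idx, ][inc] <- votes[[v + 1]][idx, ][inc] + 1L
      lastw[[v + 1]][idx, ][inc] <- w
    }
  }
  ## resolve: majority vote, ties -> value from the later window
  mask <- is.na(d)
  mask[-hiIdx, ] <- FALSE
  score0 <- votes[[1]] * (nWin + 1L) + lastw[[1]]
  score1 <- votes[[2]] * (nWin + 1L) + lastw[[2]]
  score2 <- votes[[3]] * (nWin + 1L) + lastw[[3]]
  best <- matrix(0L, nrow(d), nT)
  best[score1 > score0] <- 1L
  sBest <- pmax(score0, score1)
  best[score2 > sBest] <- 2L
  fill <- mask & (score0 + score1 + score2 > 0)
  d[fill] <- best[fill]
  new("ImputationResult",
      genotypes = GenotypeData(d, markerMapFrame(masked)),
      imputedMask = fill, method = "window_haplotype",
      trace = list(list(label = "window_haplotype", window = window,
                        overlap = overlap, nWindows = nWin)))
}
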