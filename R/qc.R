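## Chip-style quality control.  Per-SNP rules are applied in the standard
## order used for array QC in livestock: (1) defined map position,
## (2) minor allele frequency, (3) SNP call rate, (4) Hardy-Weinberg
## equilibrium; animals with low average call rate are removed last.  All
## per-SNP statistics are computed in a single pass on the full animal set
## and are NOT recomputed after animal removal; the report records this.

#' QC thresholds
#'
#' Defaults follow common chip QC for livestock panels: drop SNPs with
#' MAF < 0.0005 (strict), call rate < 0.95, Hardy-Weinberg p < 1e-5 or no
#' defined position, then drop animals with average call rate < 0.95.
#' Set any threshold to `NA` to disable that rule.
#'
#' @param maf,snpCallRate,hwePvalue,animalCallRate numeric thresholds
#'   (`NA` disables).
#' @param requirePosition drop SNPs without a defined (> 0) position.
#' @param hweTest `"chisq"` (1-df chi-square on genotype counts) or
#'   `"exact"` (exact conditional test on heterozygote counts).
#' @return named list of thresholds.
#' @export
qcThresholds <- function(maf = 0.0005, snpCallRate = 0.95, hwePvalue = 1e-5,
                         animalCallRate = 0.95, requirePosition = TRUE,
                         hweTest = c("chisq", "exact")) {
  list(maf = maf, snpCallRate = snpCallRate, hwePvalue = hwePvalue,
       animalCallRate = animalCallRate, requirePosition = requirePosition,
       hweTest = match.arg(hweTest))
}

#' Hardy-Weinberg test p-value
#'
#' @param n0,n1,n2 genotype counts (AA, AB, BB).
#' @param test `"chisq"` for the 1-df chi-square test on genotype counts,
#'   `"exact"` for the exact conditional test (sum of probabilities of
#'   heterozygote counts no more likely than the observed one).
#' @return p-value (1 for monomorphic SNPs or zero calls).
#' @export
hweTest <- function(n0, n1, n2, test = c("chisq", "exact")) {
  test <- match.arg(test)
  n <- n0 + n1 + n2
  if (n == 0) return(1)
  nB <- n1 + 2 * n2
  p <- nB / (2 * n)
  if (p == 0 || p == 1) return(1)
  if (test == "chisq") {
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((c(n0, n1, n2) - expd)^2 / expd)
    return(pchisq(stat, df = 1, lower.tail = FALSE))
  }
  ## exact: distribution of heterozygote count given allele counts
  nA <- 2 * n - nB
  minor <- min(nA, nB)
  hets <- seq(minor %% 2, minor, by = 2)
  logp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((nB - hets) / 2 + 1) + hets * log(2) +
    lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n1, hets)]
  sum(pr[pr <= obs + 1e-12])
}

#' Per-SNP and per-animal quality control
#'
#' Applies the per-SNP filters in order (position, MAF, call rate, HWE) and
#' then the per-animal call-rate filter.  Each dropped SNP records the
#' first rule it failed.  Statistics are computed once on the input (single
#' pass); the animal call rate is computed over the SNPs retained by the
#' SNP filters.
#'
#' @param gd a [GenotypeData].
#' @param thresholds from [qcThresholds()].
#' @return list with `genotypes` (filtered [GenotypeData]) and `report`
#'   (list with data.frames `snps` and `animals`, the thresholds and the
#'   single-pass flag).
#' @export
qcFilter <- function(gd, thresholds = qcThresholds()) {
  stopifnot(is(gd, "GenotypeData"))
  d <- dosages(gd)
  if (nrow(d) == 0 || ncol(d) == 0) stop("empty genotype matrix")
  mm <- markerMap(gd)
  called <- !is.na(d)
  nCalled <- rowSums(called)
  p <- rowSums(d, na.rm = TRUE) / (2 * pmax(nCalled, 1L))
  p[nCalled == 0] <- NA_real_
  maf <- pmin(p, 1 - p)
  callRate <- nCalled / ncol(d)
  n1 <- rowSums(d == 1L, na.rm = TRUE)
  n2 <- rowSums(d == 2L, na.rm = TRUE)
  n0 <- nCalled - n1 - n2
  hweP <- vapply(seq_len(nrow(d)), function(i)
    hweTest(n0[i], n1[i], n2[i], thresholds$hweTest), numeric(1))
  reason <- rep(NA_character_, nrow(d))
  fail <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- label
  }
  if (isTRUE(thresholds$requirePosition))
    fail(is.na(mm$pos) | mm$pos <= 0, "position")
  if (!is.na(thresholds$maf %||% NA))
    fail(is.na(maf) | maf < thresholds$maf, "MAF")
  if (!is.na(thresholds$snpCallRate %||% NA))
    fail(callRate < thresholds$snpCallRate, "call_rate")
  if (!is.na(thresholds$hwePvalue %||% NA))
    fail(hweP < thresholds$hwePvalue, "HWE")
  keepSnp <- is.na(reason)
  ## animal call rate over retained SNPs
  aRate <- if (any(keepSnp)) colSums(called[keepSnp, , drop = FALSE]) / sum(keepSnp)
           else rep(0, ncol(d))
  keepAnimal <- if (!is.na(thresholds$animalCallRate %||% NA))
    aRate >= thresholds$animalCallRate else rep(TRUE, ncol(d))
  report <- list(
    snps = data.frame(snp = rownames(d), maf = maf, callRate = callRate,
                      hweP = hweP, kept = keepSnp, reason = reason,
                      row.names = NULL, stringsAsFactors = FALSE),
    animals = data.frame(animal = colnames(d), callRate = aRate,
                         kept = keepAnimal, row.names = NULL,
                         stringsAsFactors = FALSE),
    thresholds = thresholds,
    singlePass = TRUE)
  if (!any(keepSnp)) stop("QC removed every SNP")
  if (!any(keepAnimal)) stop("QC removed every animal")
  out <- GenotypeData(d[keepSnp, keepAnimal, drop = FALSE],
                      markerMapFrame(gd)[keepSnp, , drop = FALSE])
  list(genotypes = out, report = report)
}

#' Write a QC report as tab-separated text
#'
#' @param report the `report` element returned by [qcFilter()].
#' @param path output file; a companion `<path>.animals` file holds the
#'   per-animal table.
#' @return the path, invisibly.
#' @export
writeQCReport <- function(report, path) {
  write.table(report$snps, path, quote = FALSE, sep = "\t", row.names = FALSE)
  write.table(report$animals, paste0(path, ".animals"), quote = FALSE,
              sep = "\t", row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
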