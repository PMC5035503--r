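## Imputation accuracy: concordance rate (CR) and allelic r-squared per
## animal or per SNP, MAF-binned rare-allele accuracy, chromosome-end
## accuracy.  CR and r2 are reported in percent; comparisons use only
## entries called in both the true and imputed matrices, optionally
## restricted by an evaluation mask (by default the masked/imputed entries
## only, since pass-through observed SNPs inflate accuracy).

.evalPairs <- function(true, imputed, evaluated) {
  dT <- dosages(true); dI <- dosages(imputed)
  .assertSameFrame(dT, dI)
  if (!identical(colnames(dT), colnames(dI)))
    stop("true and imputed matrices must cover the same animals")
  ok <- !is.na(dT) & !is.na(dI)
  if (!is.null(evaluated)) {
    if (!identical(dim(evaluated), dim(dT)))
      stop("evaluation mask does not match the genotype frame")
    ok <- ok & evaluated
  }
  list(dT = dT, dI = dI, ok = ok)
}

#' Concordance rate of imputed genotypes
#'
#' Per animal (or per SNP), `CR = 100 * #(imputed == true) / #(both
#' called)` over the evaluated entries.  Units with no comparable entries
#' get `NA` and are flagged (attribute `"undefined"`), and are excluded
#' from any mean.
#'
#' @param true,imputed [GenotypeData] on the same frame and animal set.
#' @param axis `"animal"` or `"snp"`.
#' @param evaluated optional logical matrix (SNP x animal) restricting the
#'   evaluated entries, e.g. an [imputedMask()].
#' @return named numeric vector of CR in percent, attribute `undefined`.
#' @export
concordanceRate <- function(true, imputed, axis = c("animal", "snp"),
                            evaluated = NULL) {
  axis <- match.arg(axis)
  e <- .evalPairs(true, imputed, evaluated)
  agree <- e$ok & (e$dT == e$dI)
  if (axis == "animal") { num <- colSums(agree); den <- colSums(e$ok) }
  else { num <- rowSums(agree); den <- rowSums(e$ok) }
  cr <- 100 * num / den
  cr[den == 0] <- NA_real_
  structure(cr, undefined = names(cr)[den == 0])
}

#' Allelic r-squared of imputed genotypes
#'
#' Squared Pearson correlation between true and imputed dosage vectors per
#' animal or per SNP over the comparable entries, the accuracy measure
#' least dependent on allele frequency.  Zero variance on either side
#' (e.g. a SNP monomorphic in truth) yields r2 = 0 by convention and is
#' flagged; units with fewer than two comparable entries are `NA`.
#'
#' @inheritParams concordanceRate
#' @return named numeric vector of r2 in `[0, 1]` with attributes
#'   `zeroVariance` and `undefined`.
#' @export
allelicR2 <- function(true, imputed, axis = c("animal", "snp"),
                      evaluated = NULL) {
  axis <- match.arg(axis)
  e <- .evalPairs(true, imputed, evaluated)
  margin <- if (axis == "animal") 2L else 1L
  n <- dim(e$dT)[margin]
  r2 <- numeric(n); zv <- logical(n); und <- logical(n)
  for (i in seq_len(n)) {
    ok <- if (margin == 2L) e$ok[, i] else e$ok[i, ]
    if (sum(ok) < 2) { r2[i] <- NA_real_; und[i] <- TRUE; next }
    x <- if (margin == 2L) e$dT[ok, i] else e$dT[i, ok]
    y <- if (margin == 2L) e$dI[ok, i] else e$dI[i, ok]
    if (var(x) == 0 || var(y) == 0) { r2[i] <- 0; zv[i] <- TRUE }
    else r2[i] <- cor(x, y)^2
  }
  nm <- dimnames(e$dT)[[margin]]
  structure(setNames(r2, nm), zeroVariance = nm[zv], undefined = nm[und])
}

#' Mean per-SNP r2 by MAF bin
#'
#' Bins per-SNP r2 by minor allele frequency into left-open, right-closed
#' intervals (defaults matching the standard rare-allele breakdown:
#' (0, 0.0001], (0.0001, 0.001], (0.001, 0.01], (0.01, 0.05]).  SNPs with
#' MAF 0, MAF above the top edge, or undefined values are excluded and
#' counted in the `excluded` attribute.
#'
#' @param perSnpR2 named numeric vector from [allelicR2()] (axis "snp").
#' @param freqs allele frequencies aligned to `perSnpR2` (B-allele
#'   frequencies; converted to MAF internally).
#' @param edges increasing numeric bin edges, starting at 0.
#' @return data.frame with columns `bin`, `lower`, `upper`, `n`, `meanR2`,
#'   attribute `excluded`.
#' @export
mafBinnedR2 <- function(perSnpR2, freqs, edges = c(0, 1e-4, 1e-3, 1e-2, 0.05)) {
  freqs <- freqs[names(perSnpR2)]
  maf <- pmin(freqs, 1 - freqs)
  usable <- !is.na(maf) & !is.na(perSnpR2) & maf > edges[1] &
    maf <= edges[length(edges)]
  bin <- cut(maf[usable], breaks = edges, right = TRUE)
  out <- data.frame(
    bin = levels(bin),
    lower = edges[-length(edges)],
    upper = edges[-1],
    n = as.vector(table(bin)),
    meanR2 = as.vector(tapply(perSnpR2[usable], bin, mean)),
    stringsAsFactors = FALSE)
  attr(out, "excluded") <- sum(!usable)
  out
}

#' Accuracy at chromosome ends
#'
#' Mean per-SNP r2 over the first `n` and last `n` SNPs of each chromosome
#' (map order), alongside the whole-chromosome mean.  Chromosomes with
#' fewer than `2n` SNPs split at the midpoint without double counting
#' (truncation flagged); chromosomes with no r2 values are skipped with a
#' warning.
#'
#' @param perSnpR2 named numeric vector of per-SNP r2.
#' @param map marker map `data.frame` with columns `snp`, `chrom`, `pos`
#'   (e.g. from [markerMap()]), sorted by (chromosome, position).
#' @param n SNPs per end (default 100).
#' @return data.frame with one row per chromosome: `chrom`, `nSnps`,
#'   `firstEnd`, `lastEnd`, `whole`, `truncated`.
#' @export
chromosomeEndAccuracy <- function(perSnpR2, map, n = 100L) {
  stopifnot(n >= 1)
  rows <- lapply(unique(map$chrom), function(ch) {
    snps <- map$snp[map$chrom == ch]
    r2 <- perSnpR2[snps]
    if (all(is.na(r2))) {
      warning("chromosome ", ch, " absent from the r2 vector; skipped")
      return(NULL)
    }
    m <- length(snps)
    trunc <- m < 2 * n
    nFirst <- if (trunc) ceiling(m / 2) else n
    nLast <- if (trunc) m - nFirst else n
    data.frame(chrom = ch, nSnps = m,
               firstEnd = mean(r2[seq_len(nFirst)], na.rm = TRUE),
               lastEnd = mean(r2[seq(m - nLast + 1L, m)], na.rm = TRUE),
               whole = mean(r2, na.rm = TRUE), truncated = trunc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
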