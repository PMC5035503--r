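#' Major-allele baseline imputation ("imputation by chance")
#'
#' Replaces every missing genotype by the homozygote of the more frequent
#' allele: fill 0 where `p < 0.5`, 2 where `p > 0.5`, and the heterozygote
#' 1 at an exact tie.  This is the chance baseline against which any real
#' imputer is judged; its expected concordance at a SNP is the frequency
#' of the filled genotype.
#'
#' @param masked a [GenotypeData] with missing entries to fill.
#' @param freqs allele frequencies ([alleleFrequencies()]), typically from
#'   the reference set; must be defined for every SNP that needs filling.
#' @return An [ImputationResult].
#' @export
imputeMajorAllele <- function(masked, freqs) {
  stopifnot(is(masked, "GenotypeData"))
  d <- dosages(masked)
  freqs <- freqs[rownames(d)]
  needs <- rowSums(is.na(d)) > 0
  undef <- needs & is.na(freqs)
  if (any(undef))
    stop("undefined allele frequency for SNPs to fill: ",
         paste(head(rownames(d)[undef], 5), collapse = ", "))
  fill <- ifelse(freqs < 0.5, 0L, ifelse(freqs > 0.5, 2L, 1L))
  mask <- is.na(d)
  d[mask] <- matrix(fill, nrow(d), ncol(d))[mask]
  new("ImputationResult",
      genotypes = GenotypeData(d, markerMapFrame(masked)),
      imputedMask = mask, method = "major_allele",
      trace = list(list(label = "major_allele")))
}
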