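#' Genetic map for simulation
#'
#' Physical SNP positions per chromosome together with chromosome genetic
#' lengths in Morgans, used by the gene-dropping simulator.  Positions must
#' be strictly increasing within a chromosome and genetic lengths
#' non-negative (a zero-length chromosome transmits unrecombined parental
#' haplotypes).
#'
#' @param snp,chrom,pos per-SNP id, chromosome label and 1-based bp position.
#' @param morgans named numeric, genetic length of each chromosome.
#' @return A `GeneticMap`.
#' @export
GeneticMap <- function(snp, chrom, pos, morgans) {
  new("GeneticMap",
      map = data.frame(snp = as.character(snp), chrom = as.character(chrom),
                       pos = as.integer(pos), stringsAsFactors = FALSE),
      morgans = morgans)
}

#' @rdname GeneticMap
#' @export
setClass("GeneticMap", representation(map = "data.frame", morgans = "numeric"))

setValidity("GeneticMap", function(object) {
  m <- object@map
  if (anyDuplicated(m$snp)) return("duplicated SNP ids")
  for (ch in unique(m$chrom)) {
    p <- m$pos[m$chrom == ch]
    if (any(diff(p) <= 0)) return("positions must be strictly increasing within chromosome")
    if (!ch %in% names(object@morgans)) return(paste("no genetic length for chromosome", ch))
  }
  if (any(object@morgans < 0)) return("genetic lengths must be >= 0")
  TRUE
})

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap:", nrow(object@map), "SNPs on",
      length(unique(object@map$chrom)), "chromosomes,",
      sprintf("%.1f Morgans total\n", sum(object@morgans)))
})

#' Default evenly spaced simulation map
#'
#' Builds a map with `nChrom` chromosomes of `snpsPerChrom` evenly spaced
#' SNPs each; each chromosome spans `chromBp` base pairs and
#' `morgansPerChrom` Morgans.  Chromosome labels are zero-padded so that
#' lexicographic and numeric orders agree.
#'
#' @param nChrom,snpsPerChrom,chromBp,morgansPerChrom map dimensions.
#' @return A [GeneticMap].
#' @export
defaultGeneticMap <- function(nChrom = 4L, snpsPerChrom = 500L,
                              chromBp = 1e8, morgansPerChrom = 1) {
  chrom <- sprintf("chr%02d", seq_len(nChrom))
  pos <- round(seq(1, chromBp, length.out = snpsPerChrom))
  GeneticMap(snp = sprintf("%s_snp%05d", rep(chrom, each = snpsPerChrom),
                           rep(seq_len(snpsPerChrom), nChrom)),
             chrom = rep(chrom, each = snpsPerChrom),
             pos = rep(pos, nChrom),
             morgans = setNames(rep(morgansPerChrom, nChrom), chrom))
}

#' Marker-map data.frame of a GeneticMap
#'
#' @param gmap a [GeneticMap].
#' @param alleleA,alleleB allele labels to attach.
#' @return `data.frame` usable as the `map` argument of [GenotypeData()].
#' @export
asMarkerMap <- function(gmap, alleleA = "A", alleleB = "B") {
  stopifnot(is(gmap, "GeneticMap"))
  data.frame(chrom = gmap@map$chrom, pos = gmap@map$pos,
             alleleA = alleleA, alleleB = alleleB,
             row.names = gmap@map$snp, stringsAsFactors = FALSE)
}
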