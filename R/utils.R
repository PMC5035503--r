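## Internal helpers plus small exported conveniences.

## Marker map in the exact shape the GenotypeData constructor wants
## (rownames = snp ids).
markerMapFrame <- function(gd) {
  mm <- markerMap(gd)
  rownames(mm) <- mm$snp
  mm$snp <- NULL
  mm
}

#' Subset a genotype container
#'
#' Subsets by animal ids and/or SNP ids, always preserving the canonical
#' (chromosome, position) frame order.
#'
#' @param gd a [GenotypeData].
#' @param animals,snps ids to keep (`NULL` = all).
#' @return A [GenotypeData].
#' @export
subsetGenotypes <- function(gd, animals = NULL, snps = NULL) {
  d <- dosages(gd)
  if (!is.null(animals)) {
    missing <- setdiff(animals, colnames(d))
    if (length(missing)) stop("unknown animals: ", paste(head(missing, 5), collapse = ", "))
    d <- d[, colnames(d) %in% animals, drop = FALSE]
  }
  mm <- markerMapFrame(gd)
  if (!is.null(snps)) {
    missing <- setdiff(snps, rownames(d))
    if (length(missing)) stop("unknown SNPs: ", paste(head(missing, 5), collapse = ", "))
    keep <- rownames(d) %in% snps
    d <- d[keep, , drop = FALSE]
    mm <- mm[keep, , drop = FALSE]
  }
  GenotypeData(d, mm)
}

.assertSameFrame <- function(a, b) {
  if (!identical(rownames(a), rownames(b)))
    stop("objects are not on the same SNP frame")
}
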