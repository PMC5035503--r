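## VCF I/O.  Reading goes through vcfR (GT field only); the writer emits a
## minimal plain-text VCF v4.2 with REF = A allele and ALT = B allele, so
## dosage counts the ALT allele, and "./." marks missing calls.

.readVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  snp <- fix[, "ID"]
  if (any(is.na(snp) | snp == "."))
    stop("all VCF records must carry an ID")
  if (anyDuplicated(snp)) stop("duplicated snp_id in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- ifelse(is.na(fix[, "ALT"]) | fix[, "ALT"] == ".", "B", fix[, "ALT"])
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    bad <- !is.na(g) & !(g %in% c("0/0", "0/1", "1/0", "1/1", "./."))
    if (any(bad)) stop("unsupported GT value: ", g[bad][1])
    out
  }
  d <- apply(gt, 2, code)
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(gt))
  dimnames(d) <- list(snp, colnames(gt))
  map <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    alleleA = fix[, "REF"], alleleB = alt,
                    row.names = snp, stringsAsFactors = FALSE)
  GenotypeData(d, map)
}

.writeVcf <- function(gd, path) {
  mm <- markerMap(gd)
  d <- dosages(gd)
  gtStrings <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ImputeAccuracy",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(d)), collapse = "\t")), con)
  gt <- matrix("./.", nrow(d), ncol(d))
  for (v in 0:2) gt[!is.na(d) & d == v] <- gtStrings[[as.character(v)]]
  body <- paste(mm$chrom, mm$pos, mm$snp, mm$alleleA, mm$alleleB, ".", "PASS",
                ".", "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from standard formats
#'
#' @param path for `format = "plink_text"` the file prefix (reads
#'   `<prefix>.ped` and `<prefix>.map`); for `format = "vcf"` a VCF file
#'   (plain or gzipped, GT field only).
#' @param format input format.
#' @return A [GenotypeData].  The A allele is the first listed allele
#'   (PLINK; a 6-column map fixes the assignment explicitly) or the REF
#'   allele (VCF); dosage counts the B/ALT allele.
#' @export
readGenotypes <- function(path, format = c("plink_text", "vcf")) {
  format <- match.arg(format)
  switch(format, plink_text = .readPlink(path), vcf = .readVcf(path))
}

#' Write genotypes to standard formats
#'
#' `plink_text` writes `<prefix>.ped` plus a 6-column `<prefix>.map`
#' carrying the allele labels (as PLINK .bim does) so that reading the
#' files back reproduces the dosage matrix exactly; `vcf` writes a minimal
#' GT-only VCF v4.2.
#'
#' @param gd a [GenotypeData].
#' @param path output prefix (plink) or file path (vcf).
#' @param format output format.
#' @return The written path(s), invisibly.
#' @export
writeGenotypes <- function(gd, path, format = c("plink_text", "vcf")) {
  format <- match.arg(format)
  stopifnot(is(gd, "GenotypeData"))
  switch(format, plink_text = .writePlink(gd, path), vcf = .writeVcf(gd, path))
}
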