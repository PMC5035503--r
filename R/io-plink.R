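## PLINK-style text I/O (.ped/.map).  The text dialect is simple enough to
## read and write directly: .map has chrom, snp id, genetic position (cM,
## written as 0) and bp position — optionally followed by the two allele
## labels (A, B), as in PLINK .bim files; .ped has 6 leading columns
## (family id, animal id, sire, dam, sex, phenotype) followed by two allele
## calls per SNP, "0 0" marking a missing genotype.
##
## Coding: dosage counts the B allele.  When the map carries allele columns
## they fix the assignment (and make write/read a lossless round trip);
## otherwise the first allele listed in the .ped for each SNP becomes the
## A allele.

.readPlink <- function(prefix) {
  pedFile <- paste0(prefix, ".ped")
  mapFile <- paste0(prefix, ".map")
  if (!file.exists(pedFile) || !file.exists(mapFile))
    stop("missing ", pedFile, " or ", mapFile)
  mp <- read.table(mapFile, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(mp) < 4) stop("malformed .map file: expected >= 4 columns")
  colnames(mp)[1:4] <- c("chrom", "snp", "cm", "pos")
  if (anyDuplicated(mp$snp))
    stop("duplicated snp_id in map: ", mp$snp[duplicated(mp$snp)][1])
  nS <- nrow(mp)
  hasAlleles <- ncol(mp) >= 6
  aA <- if (hasAlleles) mp[[5]] else rep(NA_character_, nS)
  aB <- if (hasAlleles) mp[[6]] else rep(NA_character_, nS)
  lines <- readLines(pedFile)
  lines <- lines[nzchar(trimws(lines))]
  d <- matrix(NA_integer_, nS, length(lines))
  animals <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * nS)
      stop("malformed .ped record at line ", i, ": expected ",
           6 + 2 * nS, " fields, found ", length(f))
    animals[i] <- f[2]
    a1 <- f[seq(7, length(f), by = 2)]
    a2 <- f[seq(8, length(f), by = 2)]
    miss <- a1 == "0" | a2 == "0"
    if (!hasAlleles) {
      ## first listed allele per SNP becomes the A allele
      new1 <- is.na(aA) & !miss
      aA[new1] <- a1[new1]
      newB <- !miss & is.na(aB) & (a1 != aA | a2 != aA)
      aB[newB] <- ifelse(a1[newB] != aA[newB], a1[newB], a2[newB])
    } else if (any(!miss & ((a1 != aA & a1 != aB) | (a2 != aA & a2 != aB)))) {
      stop("allele not in map at .ped line ", i)
    }
    dose <- (a1 != aA) + (a2 != aA)
    dose[miss] <- NA_integer_
    d[, i] <- as.integer(dose)
  }
  if (anyDuplicated(animals)) stop("duplicated animal ids in .ped")
  colnames(d) <- animals
  rownames(d) <- mp$snp
  aB[is.na(aB)] <- "B"   # monomorphic SNPs never show a second allele
  aA[is.na(aA)] <- "A"   # fully missing SNPs
  map <- data.frame(chrom = mp$chrom, pos = as.integer(mp$pos),
                    alleleA = aA, alleleB = aB, row.names = mp$snp,
                    stringsAsFactors = FALSE)
  GenotypeData(d, map)
}

.writePlink <- function(gd, prefix) {
  mm <- markerMap(gd)
  write.table(data.frame(mm$chrom, mm$snp, 0, mm$pos, mm$alleleA, mm$alleleB),
              paste0(prefix, ".map"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  d <- dosages(gd)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (j in seq_len(ncol(d))) {
    dose <- d[, j]
    a1 <- ifelse(is.na(dose), "0", ifelse(dose >= 1, mm$alleleB, mm$alleleA))
    a2 <- ifelse(is.na(dose), "0", ifelse(dose == 2, mm$alleleB, mm$alleleA))
    writeLines(paste(c("FAM1", colnames(d)[j], "0", "0", "0", "-9",
                       as.vector(rbind(a1, a2))), collapse = " "), con)
  }
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}
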