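## Export/import in the text dialects expected by external population
## imputers: a FImpute-style dosage layout (one dosage string per animal,
## "5" for missing, chip-index column for multi-density input, plus a SNP
## info file with per-chip indices) and a BEAGLE-3-style unphased layout
## (marker file plus two allele columns per animal, "?" for missing).
## Export followed by import with no external run is lossless for
## non-missing entries and round-trips missing codes.

.exportFimpute <- function(masked, reference, outdir) {
  mm <- markerMap(reference)
  lowChip <- 2L; highChip <- 1L
  snpInfo <- data.frame(SNP_ID = mm$snp, Chr = mm$chrom, Pos = mm$pos,
                        Chip1 = seq_len(nrow(mm)), Chip2 = seq_len(nrow(mm)))
  write.table(snpInfo, file.path(outdir, "snp_info.txt"), quote = FALSE,
              sep = " ", row.names = FALSE)
  dosStr <- function(d) {
    d[is.na(d)] <- 5L
    apply(d, 2, paste, collapse = "")
  }
  con <- file(file.path(outdir, "genotypes.txt"), "w")
  on.exit(close(con))
  writeLines("ID Chip Call...", con)
  writeLines(paste(animalIds(reference), highChip, dosStr(dosages(reference))), con)
  writeLines(paste(animalIds(masked), lowChip, dosStr(dosages(masked))), con)
  invisible(file.path(outdir, c("genotypes.txt", "snp_info.txt")))
}

.importFimpute <- function(dir, template) {
  lines <- readLines(file.path(dir, "genotypes.txt"))[-1]
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(trimws(lines), "[ \t]+")
  ids <- vapply(f, `[[`, "", 1)
  chips <- as.integer(vapply(f, `[[`, "", 2))
  d <- vapply(f, function(x) {
    v <- as.integer(strsplit(x[3], "")[[1]])
    v[v == 5L] <- NA_integer_
    v
  }, integer(nrow(template)))
  colnames(d) <- ids
  rownames(d) <- snpIds(template)
  list(dosage = d, chips = setNames(chips, ids))
}

.exportBeagle3 <- function(masked, reference, outdir) {
  mm <- markerMap(reference)
  write.table(data.frame(mm$snp, mm$pos, mm$alleleA, mm$alleleB),
              file.path(outdir, "markers.txt"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  writeBgl <- function(gd, path) {
    d <- dosages(gd)
    mmg <- markerMap(gd)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("I", "id", rep(colnames(d), each = 2)), collapse = " "), con)
    for (i in seq_len(nrow(d))) {
      a1 <- ifelse(is.na(d[i, ]), "?", ifelse(d[i, ] >= 1, mmg$alleleB[i], mmg$alleleA[i]))
      a2 <- ifelse(is.na(d[i, ]), "?", ifelse(d[i, ] == 2, mmg$alleleB[i], mmg$alleleA[i]))
      writeLines(paste(c("M", rownames(d)[i], as.vector(rbind(a1, a2))),
                       collapse = " "), con)
    }
  }
  writeBgl(reference, file.path(outdir, "reference.bgl"))
  writeBgl(masked, file.path(outdir, "target.bgl"))
  invisible(file.path(outdir, c("markers.txt", "reference.bgl", "target.bgl")))
}

.importBeagle3 <- function(dir, template) {
  mm <- markerMap(template)
  readBgl <- function(path) {
    lines <- readLines(path)
    hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
    ids <- unique(hdr[-(1:2)])
    d <- matrix(NA_integer_, length(lines) - 1, length(ids))
    snps <- character(length(lines) - 1)
    for (i in 2:length(lines)) {
      f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      snps[i - 1] <- f[2]
      row <- match(f[2], mm$snp)
      aB <- mm$alleleB[row]
      al <- matrix(f[-(1:2)], nrow = 2)
      dose <- colSums(al == aB)
      dose[al[1, ] == "?" | al[2, ] == "?"] <- NA_integer_
      d[i - 1, ] <- as.integer(dose)
    }
    rownames(d) <- snps; colnames(d) <- ids
    d[mm$snp, , drop = FALSE]
  }
  list(reference = readBgl(file.path(dir, "reference.bgl")),
       target = readBgl(file.path(dir, "target.bgl")))
}

#' Export genotypes for an external imputation tool
#'
#' Writes the reference and masked target genotypes in the named dialect
#' under `outdir`.  The fimpute dialect marks reference and target animals
#' with distinct chip indices (1 = high density, 2 = low) and encodes
#' missing dosages as `5`; the beagle3 dialect writes allele pairs with
#' `?` for missing.
#'
#' @param masked,reference [GenotypeData] on the same SNP frame.
#' @param format `"fimpute_dialect"` or `"beagle3_dialect"`.
#' @param outdir output directory (created if needed).
#' @return written file paths, invisibly.
#' @export
exportExternal <- function(masked, reference,
                           format = c("fimpute_dialect", "beagle3_dialect"),
                           outdir) {
  format <- match.arg(format)
  .assertSameFrame(dosages(masked), dosages(reference))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  switch(format,
         fimpute_dialect = .exportFimpute(masked, reference, outdir),
         beagle3_dialect = .exportBeagle3(masked, reference, outdir))
}

#' Import externally imputed genotypes
#'
#' Maps files written by [exportExternal()] (and possibly filled in by an
#' external tool) back onto the internal SNP frame.  Without an external
#' run, export then import reproduces the input genotypes exactly,
#' including missing entries.
#'
#' @param dir directory holding the exported files.
#' @param template a [GenotypeData] defining the SNP frame (typically the
#'   object passed as `masked` at export time).
#' @param format dialect used at export.
#' @return An [ImputationResult] for the target animals, with the chip
#'   assignment (fimpute) or reference matrix (beagle3) in the trace.
#' @export
importExternal <- function(dir, template,
                           format = c("fimpute_dialect", "beagle3_dialect")) {
  format <- match.arg(format)
  stopifnot(is(template, "GenotypeData"))
  if (format == "fimpute_dialect") {
    imp <- .importFimpute(dir, template)
    targetIds <- names(imp$chips)[imp$chips == 2L]
    d <- imp$dosage[, targetIds, drop = FALSE]
    trace <- list(list(label = "external_fimpute", chips = imp$chips))
  } else {
    imp <- .importBeagle3(dir, template)
    d <- imp$target
    trace <- list(list(label = "external_beagle3"))
  }
  was <- is.na(dosages(subsetGenotypes(template, animals = colnames(d))))
  new("ImputationResult",
      genotypes = GenotypeData(d, markerMapFrame(template)),
      imputedMask = was & !is.na(d), method = paste0("external_", format),
      trace = trace)
}
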