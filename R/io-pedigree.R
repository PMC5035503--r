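#' Pedigree text I/O
#'
#' Tab-separated text: columns `id`, `sire`, `dam`, `year` and one column
#' per breed fraction.  `NA` (or empty) parents mark founders.
#'
#' @param ped a [Pedigree].
#' @param path output file.
#' @return `writePedigree` the path invisibly; `readPedigree` a [Pedigree].
#' @export
writePedigree <- function(ped, path) {
  write.table(pedigreeTable(ped), path, quote = FALSE, sep = "\t",
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writePedigree
#' @export
readPedigree <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), check.names = FALSE,
                   colClasses = NA)
  fixed <- c("id", "sire", "dam", "year")
  if (!all(fixed %in% colnames(df)))
    stop("pedigree file must have columns id, sire, dam, year")
  breeds <- setdiff(colnames(df), fixed)
  if (!length(breeds)) stop("pedigree file has no breed-fraction columns")
  Pedigree(as.character(df$id), as.character(df$sire), as.character(df$dam),
           df$year, as.matrix(df[, breeds, drop = FALSE]))
}
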