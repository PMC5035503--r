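#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.DOSAGE_VALUES <- c(0L, 1L, 2L)

## ---------------------------------------------------------------------------
## GenotypeData: SNP x animal dosage matrix bound to a marker map
## ---------------------------------------------------------------------------

#' Genotype container: dosages bound to a marker map
#'
#' `GenotypeData` extends [SummarizedExperiment::SummarizedExperiment]: rows
#' are SNPs, columns are animals, and the single assay `"dosage"` holds
#' 0/1/2 dosages of the B allele (`AA = 0`, `AB = 1`, `BB = 2`) with `NA`
#' for missing calls.  The marker map (chromosome, 1-based bp position,
#' allele labels) lives in `rowData` and is kept sorted by
#' (chromosome, position), the package's canonical SNP order.
#'
#' @param dosage integer matrix, SNPs in rows and animals in columns, values
#'   in \{0, 1, 2, `NA`\}.  Row names are SNP ids, column names animal ids.
#' @param map `data.frame` with one row per SNP (matched to `dosage` by row
#'   name or by order) and columns `chrom`, `pos`, `alleleA`, `alleleB`.
#'
#' @return A `GenotypeData` object.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("a1", "a2")))
#' map <- data.frame(chrom = "1", pos = c(100L, 200L),
#'                   alleleA = "A", alleleB = "B", row.names = c("s1", "s2"))
#' gd <- GenotypeData(d, map)
#' dosages(gd)
#' @export
GenotypeData <- function(dosage, map) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) stop("dosage matrix must have SNP row names")
  if (is.null(colnames(dosage))) {
    if (ncol(dosage) > 0) stop("dosage matrix must have animal column names")
    colnames(dosage) <- character(0)
  }
  map <- as.data.frame(map)
  req <- c("chrom", "pos", "alleleA", "alleleB")
  if (!all(req %in% colnames(map)))
    stop("map must have columns: ", paste(req, collapse = ", "))
  if (!is.null(rownames(map)) && !all(rownames(map) == as.character(seq_len(nrow(map))))) {
    if (!setequal(rownames(map), rownames(dosage)))
      stop("map row names do not match dosage SNP ids")
    map <- map[rownames(dosage), , drop = FALSE]
  } else if (nrow(map) != nrow(dosage)) {
    stop("map has ", nrow(map), " rows but dosage has ", nrow(dosage), " SNPs")
  }
  ord <- order(as.character(map$chrom), map$pos)
  dosage <- dosage[ord, , drop = FALSE]
  map <- map[ord, , drop = FALSE]
  rd <- DataFrame(chrom = as.character(map$chrom),
                  pos = as.integer(map$pos),
                  alleleA = as.character(map$alleleA),
                  alleleB = as.character(map$alleleB),
                  row.names = rownames(dosage))
  se <- SummarizedExperiment(assays = list(dosage = dosage), rowData = rd)
  new("GenotypeData", se)
}

#' @rdname GenotypeData
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is missing")
  d <- assay(object, "dosage")
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% .DOSAGE_VALUES))
    return("dosages must be 0, 1, 2 or NA")
  rd <- rowData(object)
  req <- c("chrom", "pos", "alleleA", "alleleB")
  if (!all(req %in% colnames(rd)))
    return(paste("rowData must contain", paste(req, collapse = ", ")))
  if (anyDuplicated(rownames(object))) return("duplicated SNP ids")
  if (anyDuplicated(colnames(object))) return("duplicated animal ids")
  if (any(!is.na(rd$pos) & rd$pos <= 0)) return("positions must be > 0 where defined")
  ord <- order(as.character(rd$chrom), rd$pos)
  if (!identical(ord, seq_len(nrow(object))))
    return("SNPs must be sorted by (chromosome, position)")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeData", function(x, ...) assay(x, "dosage"))

#' @rdname accessors
#' @export
setMethod("markerMap", "GenotypeData", function(x, ...) {
  df <- as.data.frame(rowData(x))
  df$snp <- rownames(x)
  df[, c("snp", "chrom", "pos", "alleleA", "alleleB")]
})

#' @rdname accessors
#' @export
setMethod("animalIds", "GenotypeData", function(x, ...) colnames(x))

#' @rdname accessors
#' @export
setMethod("snpIds", "GenotypeData", function(x, ...) rownames(x))

setMethod("show", "GenotypeData", function(object) {
  d <- assay(object, "dosage")
  miss <- mean(is.na(d))
  cat("GenotypeData:", nrow(object), "SNPs x", ncol(object), "animals\n")
  cat("  chromosomes:", paste(unique(rowData(object)$chrom), collapse = ", "), "\n")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
})

## ---------------------------------------------------------------------------
## PanelDef: named, ordered SNP subset
## ---------------------------------------------------------------------------

#' SNP panel definition
#'
#' An ordered subset of SNP ids defining one genotyping density.  Panels of
#' increasing density are usually nested (low is a subset of medium is a
#' subset of high), which [buildPanels()] can verify.
#'
#' @param name panel label, e.g. `"5K"`.
#' @param snps character vector of SNP ids, in map order.
#' @return A `PanelDef` object.
#' @export
PanelDef <- function(name, snps) {
  new("PanelDef", name = as.character(name), snps = as.character(snps))
}

#' @rdname PanelDef
#' @export
setClass("PanelDef", representation(name = "character", snps = "character"))

setValidity("PanelDef", function(object) {
  if (length(object@name) != 1L) return("name must be a single string")
  if (length(object@snps) == 0L) return("panel has no SNPs")
  if (anyDuplicated(object@snps)) return("duplicated SNP ids in panel")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("panelSnps", "PanelDef", function(x, ...) x@snps)

setMethod("show", "PanelDef", function(object) {
  cat("PanelDef '", object@name, "': ", length(object@snps), " SNPs\n", sep = "")
})

## ---------------------------------------------------------------------------
## Pedigree
## ---------------------------------------------------------------------------

#' Pedigree with breed composition
#'
#' Animal, sire, dam, birth year and a breed-composition vector per animal.
#' Founders have `NA` parents.  Breed fractions must sum to 1 per animal,
#' and every non-founder's parents must be born in strictly earlier years,
#' which also guarantees that no animal is its own ancestor.
#'
#' @param id,sire,dam character vectors; `NA` in `sire`/`dam` marks founders.
#' @param year integer birth years.
#' @param breedComp numeric matrix, animals x breeds, rows summing to 1.
#' @return A `Pedigree` object.
#' @export
Pedigree <- function(id, sire, dam, year, breedComp) {
  breedComp <- as.matrix(breedComp)
  rownames(breedComp) <- id
  new("Pedigree", id = as.character(id), sire = as.character(sire),
      dam = as.character(dam), year = as.integer(year), breedComp = breedComp)
}

#' @rdname Pedigree
#' @export
setClass("Pedigree", representation(id = "character", sire = "character",
                                    dam = "character", year = "integer",
                                    breedComp = "matrix"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@year) != n || nrow(object@breedComp) != n)
    return("field lengths differ")
  if (anyDuplicated(object@id)) return("duplicated animal ids")
  if (any(abs(rowSums(object@breedComp) - 1) > 1e-6))
    return("breed fractions must sum to 1")
  yr <- setNames(object@year, object@id)
  for (p in list(object@sire, object@dam)) {
    known <- !is.na(p)
    if (any(!(p[known] %in% object@id))) return("parent not present in pedigree")
    if (any(yr[p[known]] >= object@year[known]))
      return("parents must be born in strictly earlier years")
  }
  TRUE
})

#' Pedigree as a data.frame
#'
#' @param ped a [Pedigree].
#' @return `data.frame` with id, sire, dam, year and one column per breed
#'   fraction.
#' @export
pedigreeTable <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  data.frame(id = ped@id, sire = ped@sire, dam = ped@dam, year = ped@year,
             ped@breedComp, check.names = FALSE, row.names = NULL)
}

setMethod("show", "Pedigree", function(object) {
  founders <- sum(is.na(object@sire) & is.na(object@dam))
  cat("Pedigree:", length(object@id), "animals (", founders, "founders ),",
      ncol(object@breedComp), "breeds, years",
      min(object@year), "-", max(object@year), "\n")
})

## ---------------------------------------------------------------------------
## HaplotypeSet
## ---------------------------------------------------------------------------

#' Phased haplotypes
#'
#' Binary allele array (SNP x 2 haplotypes x animal); summing the two
#' haplotypes per animal yields a valid 0/1/2 genotype matrix.
#'
#' @param alleles integer array with dim (nSnps, 2, nAnimals) and dimnames
#'   for SNPs (1st) and animals (3rd).
#' @return A `HaplotypeSet` object.
#' @export
HaplotypeSet <- function(alleles) {
  storage.mode(alleles) <- "integer"
  new("HaplotypeSet", alleles = alleles)
}

#' @rdname HaplotypeSet
#' @export
setClass("HaplotypeSet", representation(alleles = "array"))

setValidity("HaplotypeSet", function(object) {
  a <- object@alleles
  if (length(dim(a)) != 3L || dim(a)[2] != 2L)
    return("alleles must be an (nSnps, 2, nAnimals) array")
  if (!all(a %in% c(0L, 1L))) return("alleles must be 0/1")
  if (is.null(dimnames(a)[[1]]) || is.null(dimnames(a)[[3]]))
    return("SNP and animal dimnames required")
  TRUE
})

setMethod("show", "HaplotypeSet", function(object) {
  d <- dim(object@alleles)
  cat("HaplotypeSet:", d[1], "SNPs x", d[3], "animals (phased)\n")
})

#' Collapse haplotypes to genotypes
#'
#' @param haps a [HaplotypeSet].
#' @param map marker map `data.frame` (see [GenotypeData()]).
#' @return A [GenotypeData] with dosage = hap1 + hap2.
#' @export
haplotypesToGenotypes <- function(haps, map) {
  stopifnot(is(haps, "HaplotypeSet"))
  a <- haps@alleles
  d <- a[, 1L, , drop = TRUE] + a[, 2L, , drop = TRUE]
  if (is.null(dim(d))) d <- matrix(d, nrow = dim(a)[1])
  dimnames(d) <- dimnames(a)[c(1, 3)]
  GenotypeData(d, map)
}

## ---------------------------------------------------------------------------
## GRM: genomic relationship matrix
## ---------------------------------------------------------------------------

#' Genomic relationship matrix container
#'
#' Holds the symmetric relationship matrix `G`, the centered incidence
#' matrix `X` it was built from (animals x SNPs, dosage minus twice the
#' allele frequency, missing entries zero), the per-SNP allele frequencies
#' and the scaling constant `2 * sum(p * (1 - p))`.
#'
#' @seealso [computeG()]
#' @export
setClass("GRM", representation(G = "matrix", X = "matrix",
                               freqs = "numeric", scale = "numeric"))

setValidity("GRM", function(object) {
  if (!isSymmetric(unname(object@G), tol = 1e-8)) return("G must be symmetric")
  if (object@scale <= 0) return("scaling constant must be > 0")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("relMatrix", "GRM", function(x, ...) x@G)

#' @rdname accessors
#' @export
setMethod("animalIds", "GRM", function(x, ...) rownames(x@G))

setMethod("show", "GRM", function(object) {
  cat("GRM:", nrow(object@G), "animals,", length(object@freqs), "SNPs,",
      sprintf("scale 2*sum(p(1-p)) = %.2f\n", object@scale))
  dg <- diag(object@G)
  cat(sprintf("  diagonal: mean %.3f [%.3f, %.3f]\n",
              mean(dg), min(dg), max(dg)))
})

## ---------------------------------------------------------------------------
## ImputationResult
## ---------------------------------------------------------------------------

#' Result of an imputation run
#'
#' Wraps the filled genotype matrix together with a logical mask flagging
#' which entries were imputed (observed low-density genotypes always pass
#' through unchanged), the method label and a step trace for two-step runs.
#'
#' @export
setClass("ImputationResult",
         representation(genotypes = "GenotypeData", imputedMask = "matrix",
                        method = "character", trace = "list"))

#' @rdname accessors
#' @export
setMethod("dosages", "ImputationResult", function(x, ...) dosages(x@genotypes))

#' @rdname accessors
#' @export
setMethod("imputedMask", "ImputationResult", function(x, ...) x@imputedMask)

#' Imputed genotypes of a result
#' @param x an `ImputationResult`.
#' @return The [GenotypeData] with filled entries.
#' @export
imputedGenotypes <- function(x) {
  stopifnot(is(x, "ImputationResult"))
  x@genotypes
}

setMethod("show", "ImputationResult", function(object) {
  cat("ImputationResult (", object@method, "): ",
      nrow(object@genotypes), " SNPs x ", ncol(object@genotypes),
      " animals, ", sum(object@imputedMask), " entries imputed\n", sep = "")
  if (length(object@trace))
    cat("  steps:", paste(vapply(object@trace, `[[`, "", "label"),
                          collapse = " -> "), "\n")
})

## ---------------------------------------------------------------------------
## Scenario
## ---------------------------------------------------------------------------

#' Imputation scenario
#'
#' A reference/target/panel configuration: which animals form the reference
#' set, which are masked to the source panel and imputed back to the target
#' panel, the imputation method configuration, and optional selection rules
#' (oldest-as-reference by birth year; exclusion of reference animals whose
#' genomic relationship to any target exceeds a cut-off, 0.45 by default in
#' the field's practice).
#'
#' @param name scenario label.
#' @param reference,targets character vectors of animal ids (reference pool
#'   and animals to impute); must be disjoint.
#' @param sourcePanel,targetPanel [PanelDef]s; the source panel must be a
#'   strict subset of the target panel.
#' @param method list configuring the imputer: `list(name = "window",
#'   window = 32, overlap = 8)` or `list(name = "major")`.
#' @param selection list of optional rules: `nReference` (keep the n oldest
#'   reference animals by birth year; requires a pedigree at run time),
#'   `maxRelatedness` (drop reference animals with G above this to any
#'   target), `seed` (for any sampling).
#' @return A `Scenario`.
#' @export
Scenario <- function(name, reference, targets, sourcePanel, targetPanel,
                     method = list(name = "window", window = 200L, overlap = 150L),
                     selection = list()) {
  new("Scenario", name = name, reference = as.character(reference),
      targets = as.character(targets), sourcePanel = sourcePanel,
      targetPanel = targetPanel, method = method, selection = selection)
}

#' @rdname Scenario
#' @export
setClass("Scenario",
         representation(name = "character", reference = "character",
                        targets = "character", sourcePanel = "PanelDef",
                        targetPanel = "PanelDef", method = "list",
                        selection = "list"))

setValidity("Scenario", function(object) {
  if (length(intersect(object@reference, object@targets)))
    return("reference and target sets must be disjoint")
  if (!all(object@sourcePanel@snps %in% object@targetPanel@snps))
    return("source panel must be a subset of the target panel")
  TRUE
})

setMethod("show", "Scenario", function(object) {
  cat("Scenario '", object@name, "': ", length(object@reference),
      " reference, ", length(object@targets), " targets, ",
      object@sourcePanel@name, " -> ", object@targetPanel@name,
      " (", object@method$name, ")\n", sep = "")
})
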