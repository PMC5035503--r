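#' Run an imputation scenario end to end
#'
#' Applies the scenario's selection rules, masks the target animals to the
#' source panel, imputes back to the target panel with the configured
#' engine, and evaluates concordance rate and allelic r2 per animal and
#' per SNP.  Selection rules: `nReference` keeps the n oldest reference
#' animals by birth year (requires `pedigree`; ties resolved by id);
#' `maxRelatedness` drops reference animals whose genomic relationship
#' (computed from the truth at target-panel density, allele frequencies
#' over the union of reference and targets) to any target exceeds the
#' cut-off.  All randomness is owned by the scenario's `selection$seed`.
#'
#' @param scenario a [Scenario].
#' @param truth a [GenotypeData] holding true genotypes at target-panel
#'   density for both reference and target animals.
#' @param pedigree optional [Pedigree] for birth-year selection.
#' @param evaluated `"masked"` (default: only entries hidden by the source
#'   panel masking are scored, the stricter convention) or `"all"`
#'   (include pass-through observed entries).
#' @return list ("AccuracyReport") with `perAnimal` and `perSnp`
#'   data.frames, `overall` (mean CR and r2 in percent), `evaluated`,
#'   `emptyEvaluation` flag, `droppedReference` ids, the `scenario` name
#'   and the [ImputationResult] in `imputation`.
#' @export
runScenario <- function(scenario, truth, pedigree = NULL,
                        evaluated = c("masked", "all")) {
  stopifnot(is(scenario, "Scenario"), is(truth, "GenotypeData"))
  evaluated <- match.arg(evaluated)
  reference <- scenario@reference
  targets <- scenario@targets
  missing <- setdiff(c(reference, targets), animalIds(truth))
  if (length(missing))
    stop("scenario stage [select]: animals absent from truth: ",
         paste(head(missing, 5), collapse = ", "))
  sel <- scenario@selection
  dropped <- character(0)
  if (!is.null(sel$nReference)) {
    if (is.null(pedigree))
      stop("scenario stage [select]: nReference rule needs a pedigree")
    yr <- setNames(pedigree@year, pedigree@id)[reference]
    reference <- reference[order(yr, reference)][seq_len(min(sel$nReference,
                                                             length(reference)))]
  }
  if (!is.null(sel$maxRelatedness)) {
    union <- c(reference, targets)
    gTrim <- subsetGenotypes(truth, animals = union,
                             snps = scenario@targetPanel@snps)
    grm <- computeG(gTrim, alleleFrequencies(gTrim))
    G <- relMatrix(grm)
    tooClose <- vapply(reference, function(r)
      max(G[r, targets]) > sel$maxRelatedness, logical(1))
    dropped <- reference[tooClose]
    reference <- reference[!tooClose]
    if (!length(reference))
      stop("scenario stage [select]: relatedness exclusion emptied the reference set")
  }
  truthT <- subsetGenotypes(truth, animals = targets)
  masked <- maskToPanel(truthT, scenario@sourcePanel)
  refG <- subsetGenotypes(truth, animals = reference)
  method <- scenario@method
  result <- switch(
    method$name %||% "window",
    major = imputeMajorAllele(
      maskToPanel(masked, scenario@targetPanel),
      alleleFrequencies(refG)),
    window = imputeWindowHaplotype(
      masked, refG, scenario@sourcePanel, scenario@targetPanel,
      window = method$window %||% 200L, overlap = method$overlap %||% 150L),
    stop("scenario stage [impute]: unknown method '", method$name, "'"))
  imput <- imputedGenotypes(result)
  onTarget <- snpIds(truthT) %in% scenario@targetPanel@snps
  evalMask <- if (evaluated == "masked") imputedMask(result) & onTarget else {
    m <- matrix(TRUE, nrow(dosages(truthT)), ncol(dosages(truthT)))
    m[!onTarget, ] <- FALSE
    m
  }
  empty <- !any(evalMask)
  if (empty) {   # nothing was imputed: fall back to scoring the target panel
    evalMask <- matrix(onTarget, nrow(dosages(truthT)), ncol(dosages(truthT)))
  }
  crA <- concordanceRate(truthT, imput, "animal", evalMask)
  r2A <- allelicR2(truthT, imput, "animal", evalMask)
  crS <- concordanceRate(truthT, imput, "snp", evalMask)
  r2S <- allelicR2(truthT, imput, "snp", evalMask)
  list(perAnimal = data.frame(animal = names(crA), cr = as.vector(crA),
                              r2 = as.vector(r2A), row.names = NULL,
                              stringsAsFactors = FALSE),
       perSnp = data.frame(snp = names(crS), cr = as.vector(crS),
                           r2 = as.vector(r2S), row.names = NULL,
                           stringsAsFactors = FALSE),
       overall = c(cr = mean(crA, na.rm = TRUE),
                   r2 = 100 * mean(r2A, na.rm = TRUE)),
       evaluated = evaluated, emptyEvaluation = empty,
       droppedReference = dropped, reference = reference,
       scenario = scenario@name, imputation = result)
}

#' Per-animal accuracy table sorted for plotting
#'
#' Accuracy-per-animal data sorted from the highest to the lowest value,
#' the standard convention for imputation accuracy figures.
#'
#' @param report a report from [runScenario()].
#' @param measure `"cr"` or `"r2"`.
#' @return data.frame with `rank`, `animal` and the measure.
#' @export
accuracyPlotData <- function(report, measure = c("cr", "r2")) {
  measure <- match.arg(measure)
  df <- report$perAnimal[order(-report$perAnimal[[measure]]), ]
  data.frame(rank = seq_len(nrow(df)), animal = df$animal,
             value = df[[measure]], row.names = NULL,
             stringsAsFactors = FALSE)
}
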