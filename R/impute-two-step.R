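#' Two-step imputation: low -> mid -> high
#'
#' Step 1 imputes targets from the low to the mid panel against a (usually
#' large) mid-density reference; step 2 imputes the step-1 output from mid
#' to high against the high-density reference.  With strictly nested panels
#' this mirrors the strategy of imputing first to an intermediate density
#' for which many more reference animals exist.  The step trace records
#' both stages.
#'
#' @param maskedLow targets: [GenotypeData] observed on the low panel.
#' @param referenceMid [GenotypeData] genotyped on the mid panel.
#' @param referenceHigh [GenotypeData] genotyped on the high panel.
#' @param panels list of three [PanelDef]s (low, mid, high), nested.
#' @param window,overlap window parameters for both steps.
#' @return An [ImputationResult] with a two-stage trace.
#' @export
imputeTwoStep <- function(maskedLow, referenceMid, referenceHigh, panels,
                          window = 200L, overlap = 150L) {
  if (length(panels) != 3) stop("panels must be list(low, mid, high)")
  low <- panels[[1]]; mid <- panels[[2]]; high <- panels[[3]]
  if (!all(low@snps %in% mid@snps) || !all(mid@snps %in% high@snps))
    stop("panels must be nested: low within mid within high")
  step1 <- imputeWindowHaplotype(maskedLow, referenceMid, low, mid,
                                 window = window, overlap = overlap)
  step2 <- imputeWindowHaplotype(imputedGenotypes(step1), referenceHigh,
                                 mid, high, window = window, overlap = overlap)
  mask <- step1@imputedMask | step2@imputedMask
  new("ImputationResult", genotypes = imputedGenotypes(step2),
      imputedMask = mask, method = "two_step_window",
      trace = list(list(label = sprintf("step1:%s->%s", low@name, mid@name),
                        window = window, overlap = overlap),
                   list(label = sprintf("step2:%s->%s", mid@name, high@name),
                        window = window, overlap = overlap)))
}
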