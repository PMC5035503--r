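#' Breed plan for the population simulator
#'
#' Describes a multi-breed population: breed labels with a per-breed
#' divergence parameter (a Balding-Nichols `Fst`-like scalar in `[0, 1)`
#' governing drift of breed allele frequencies away from the shared base
#' frequencies), founder counts per breed, and per-generation crossing
#' rules.  Each rule mates animals whose breed-composition vector matches a
#' target dam (and sire) composition and produces `n` offspring whose
#' composition is the mean of the parents'.
#'
#' @param breeds character vector of breed labels.
#' @param divergence named numeric in `[0, 1)`, one entry per breed.
#' @param founders named positive integers, founder count per breed (>= 2
#'   for any breed used in crosses).
#' @param matings list of generations; each generation is a list of rules
#'   `list(dam = <named composition>, sire = <named composition>, n = <int>)`.
#'   Compositions are named numeric vectors over `breeds` summing to 1;
#'   parents are drawn among earlier-born animals whose composition matches
#'   within `tol` (max absolute difference).
#' @param tol matching tolerance for parent selection.
#' @return A `BreedPlan`.
#' @examples
#' plan <- BreedPlan(breeds = c("romney", "terminal"),
#'                   divergence = c(romney = 0.05, terminal = 0.35),
#'                   founders = c(romney = 20, terminal = 10),
#'                   matings = list(list(
#'                     list(dam = c(romney = 1, terminal = 0),
#'                          sire = c(romney = 1, terminal = 0), n = 30))))
#' @export
BreedPlan <- function(breeds, divergence, founders, matings, tol = 0.13) {
  new("BreedPlan", breeds = as.character(breeds),
      divergence = divergence[breeds], founders = as.integer(founders[breeds]),
      matings = matings, tol = tol)
}

#' @rdname BreedPlan
#' @export
setClass("BreedPlan",
         representation(breeds = "character", divergence = "numeric",
                        founders = "integer", matings = "list",
                        tol = "numeric"))

setValidity("BreedPlan", function(object) {
  b <- object@breeds
  if (length(object@divergence) != length(b) || any(is.na(object@divergence)))
    return("divergence must be named over all breeds")
  if (any(object@divergence < 0 | object@divergence >= 1))
    return("divergence must be in [0, 1)")
  if (length(object@founders) != length(b) || any(is.na(object@founders)) ||
      any(object@founders < 2L))
    return("founder counts must be >= 2 per breed")
  for (gen in object@matings) for (rule in gen) {
    for (side in c("dam", "sire")) {
      comp <- rule[[side]]
      if (!all(names(comp) %in% b))
        return(paste("crossing rule references unknown breed:",
                     paste(setdiff(names(comp), b), collapse = ", ")))
      if (abs(sum(comp) - 1) > 1e-6)
        return("rule breed proportions must sum to 1")
    }
    if (is.null(rule$n) || rule$n < 1) return("rule offspring count must be >= 1")
  }
  TRUE
})

setMethod("show", "BreedPlan", function(object) {
  cat("BreedPlan:", paste(object@breeds, collapse = ", "), "\n")
  cat("  founders:", paste(object@founders, collapse = "/"),
      " divergence:", paste(format(object@divergence), collapse = "/"), "\n")
  cat("  generations:", length(object@matings), "\n")
})

.comp <- function(plan, ...) {
  v <- setNames(numeric(length(plan@breeds)), plan@breeds)
  spec <- c(...)
  v[names(spec)] <- spec
  v
}

#' Default multi-breed plan
#'
#' The shipped study conditions: two related dual-purpose breeds
#' (`romney`-like and `coopworth`-like, low divergence), a composite line
#' bred from crosses between them, and one weakly related `terminal` breed
#' with near-zero cross-membership that never enters the crosses — so that
#' cross-breed reference/target pairings with near-zero genomic relatedness
#' exist in every default population.  Three discrete generations of matings
#' on top of the founders; birth years follow the generation index.
#'
#' @param scale multiplies all founder and offspring counts (rounded up).
#' @return A [BreedPlan].
#' @export
defaultBreedPlan <- function(scale = 1) {
  s <- function(n) as.integer(ceiling(n * scale))
  breeds <- c("romney", "coopworth", "terminal")
  pure <- function(b) setNames(as.numeric(breeds == b), breeds)
  gen <- function(nR, nC, nT, nX, composite = FALSE) {
    rules <- list(
      list(dam = pure("romney"), sire = pure("romney"), n = s(nR)),
      list(dam = pure("coopworth"), sire = pure("coopworth"), n = s(nC)),
      list(dam = pure("terminal"), sire = pure("terminal"), n = s(nT)))
    if (composite) {
      half <- setNames(c(0.5, 0.5, 0), breeds)
      rules <- c(rules, list(list(dam = half, sire = half, n = s(nX))))
    } else {
      rules <- c(rules, list(list(dam = pure("romney"),
                                  sire = pure("coopworth"), n = s(nX))))
    }
    rules
  }
  BreedPlan(breeds = breeds,
            divergence = c(romney = 0.05, coopworth = 0.08, terminal = 0.35),
            founders = c(romney = s(40), coopworth = s(30), terminal = s(20)),
            matings = list(gen(60, 40, 25, 20, composite = FALSE),
                           gen(60, 40, 25, 20, composite = TRUE),
                           gen(60, 40, 25, 20, composite = TRUE)))
}
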