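## Synthetic multi-breed population generator: Balding-Nichols founder
## frequencies, discrete-generation pedigree, gene dropping with Haldane
## (no-interference) recombination, and genotype noise/missingness.

#' Per-breed founder allele frequencies
#'
#' Draws a base allele-frequency vector from `baseDist` and diverges it per
#' breed under the Balding-Nichols beta model: for divergence `c > 0` the
#' breed frequency at a SNP with base frequency `p` is drawn from
#' `Beta(p(1-c)/c, (1-p)(1-c)/c)`; `c = 0` breeds share the base vector
#' exactly.  Breeds are processed in plan order so draws are reproducible
#' for a fixed seed.
#'
#' @param nSnps number of SNPs.
#' @param plan a [BreedPlan] (supplies breed labels and divergence).
#' @param baseDist function of `n` returning base B-allele frequencies in
#'   (0, 1).  The default `Beta(0.5, 0.5)` spectrum places mass at both
#'   common and rare frequencies, including minor allele frequencies below
#'   0.001.
#' @param seed integer RNG seed.
#' @return numeric matrix, SNPs x breeds, of B-allele frequencies, with the
#'   base vector attached as attribute `"base"`.
#' @export
simulateFounderFrequencies <- function(nSnps, plan,
                                       baseDist = function(n) rbeta(n, 0.5, 0.5),
                                       seed = 1L) {
  stopifnot(is(plan, "BreedPlan"), nSnps >= 1)
  if (any(plan@divergence < 0 | plan@divergence >= 1))
    stop("divergence must be in [0, 1)")
  set.seed(seed)
  base <- baseDist(nSnps)
  if (any(base < 0 | base > 1)) stop("base frequencies must lie in [0, 1]")
  freqs <- matrix(NA_real_, nSnps, length(plan@breeds),
                  dimnames = list(NULL, plan@breeds))
  for (b in plan@breeds) {
    cc <- plan@divergence[[b]]
    freqs[, b] <- if (cc == 0) base else
      rbeta(nSnps, base * (1 - cc) / cc, (1 - base) * (1 - cc) / cc)
  }
  structure(freqs, base = base)
}

#' Simulate a pedigree from a breed plan
#'
#' Founders (generation 0) are purebred; each subsequent generation applies
#' the plan's crossing rules, sampling dams and sires (with replacement,
#' dam != sire) among all earlier-born animals whose breed composition
#' matches the rule within the plan tolerance.  Offspring composition is
#' the mean of the parents'; birth year is `baseYear + generation`.
#'
#' @param plan a [BreedPlan].
#' @param seed integer RNG seed.
#' @param baseYear founder birth year.
#' @return A [Pedigree].
#' @export
simulatePedigree <- function(plan, seed = 1L, baseYear = 2000L) {
  stopifnot(is(plan, "BreedPlan"))
  set.seed(seed)
  breeds <- plan@breeds
  id <- character(0); sire <- character(0); dam <- character(0)
  year <- integer(0); comp <- NULL
  for (b in breeds) {
    n <- plan@founders[[match(b, breeds)]]
    id <- c(id, sprintf("%s_F%03d", b, seq_len(n)))
    sire <- c(sire, rep(NA_character_, n)); dam <- c(dam, rep(NA_character_, n))
    year <- c(year, rep(baseYear, n))
    m <- matrix(as.numeric(breeds == b), n, length(breeds), byrow = TRUE)
    comp <- rbind(comp, m)
  }
  colnames(comp) <- breeds
  counter <- 0L
  for (g in seq_along(plan@matings)) {
    gy <- baseYear + g
    ## candidates: all animals born strictly earlier
    for (rule in plan@matings[[g]]) {
      for (side in c("dam", "sire")) {
        unknown <- setdiff(names(rule[[side]]), breeds)
        if (length(unknown))
          stop("crossing rule references unknown breed: ",
               paste(unknown, collapse = ", "))
      }
      eligible <- which(year < gy)
      matches <- function(target) {
        tv <- setNames(numeric(length(breeds)), breeds)
        tv[names(target)] <- target
        eligible[apply(abs(comp[eligible, , drop = FALSE] -
                             matrix(tv, length(eligible), length(breeds),
                                    byrow = TRUE)), 1, max) <= plan@tol]
      }
      dams <- matches(rule$dam); sires <- matches(rule$sire)
      if (!length(dams) || !length(sires))
        stop("no animals match a crossing rule in generation ", g)
      for (k in seq_len(rule$n)) {
        d <- dams[sample.int(length(dams), 1L)]
        s <- sires[sample.int(length(sires), 1L)]
        if (length(union(dams, sires)) > 1L)
          while (s == d) s <- sires[sample.int(length(sires), 1L)]
        counter <- counter + 1L
        id <- c(id, sprintf("G%d_%05d", g, counter))
        dam <- c(dam, id[d]); sire <- c(sire, id[s]); year <- c(year, gy)
        comp <- rbind(comp, (comp[d, ] + comp[s, ]) / 2)
      }
    }
  }
  Pedigree(id, sire, dam, year, comp)
}

#' Founder haplotypes from breed frequencies
#'
#' Each founder's two haplotypes carry independent Bernoulli draws of the B
#' allele at its breed's frequency.  Founders with mixed composition draw
#' at the composition-weighted mean frequency.
#'
#' @param ped a [Pedigree].
#' @param freqs SNPs x breeds frequency matrix from
#'   [simulateFounderFrequencies()].
#' @param gmap a [GeneticMap] (supplies SNP ids).
#' @param seed integer RNG seed.
#' @return A [HaplotypeSet] covering the founders.
#' @export
simulateFounderHaplotypes <- function(ped, freqs, gmap, seed = 1L) {
  stopifnot(is(ped, "Pedigree"), is(gmap, "GeneticMap"))
  set.seed(seed)
  founders <- ped@id[is.na(ped@sire) & is.na(ped@dam)]
  nS <- nrow(gmap@map)
  if (nrow(freqs) != nS) stop("frequency table does not cover the map")
  a <- array(0L, dim = c(nS, 2L, length(founders)),
             dimnames = list(gmap@map$snp, NULL, founders))
  for (i in seq_along(founders)) {
    w <- ped@breedComp[founders[i], colnames(freqs)]
    p <- as.vector(freqs %*% w)
    a[, 1L, i] <- rbinom(nS, 1L, p)
    a[, 2L, i] <- rbinom(nS, 1L, p)
  }
  HaplotypeSet(a)
}

## Crossover breakpoint positions (bp) for one meiosis on one chromosome:
## count ~ Poisson(length in Morgans), positions uniform on [lo, hi]
## (Haldane model, no interference).
.crossoverBreaks <- function(morgans, lo, hi) {
  k <- rpois(1L, morgans)
  if (k == 0L) return(numeric(0))
  sort(runif(k, lo, hi))
}

## One transmitted gamete: recombinant mosaic of the parent's two haplotypes.
.dropGamete <- function(hapPair, pos, morgans) {
  breaks <- .crossoverBreaks(morgans, min(pos), max(pos))
  start <- sample.int(2L, 1L)
  src <- (start - 1L + findInterval(pos, breaks)) %% 2L + 1L
  ifelse(src == 1L, hapPair[, 1L], hapPair[, 2L])
}

#' Gene dropping down a pedigree
#'
#' Transmits founder haplotypes down the pedigree: each meiosis draws a
#' Poisson number of crossovers per chromosome (mean = genetic length in
#' Morgans, Haldane model) at positions uniform on the chromosome's bp
#' span, and the transmitted gamete is the corresponding mosaic of the
#' parent's two haplotypes.  Error-free output is Mendelian-consistent:
#' parent-offspring pairs have zero opposing homozygotes.
#'
#' @param ped a [Pedigree]; all founders must be present in `founderHaps`.
#' @param founderHaps a [HaplotypeSet] for the founders.
#' @param gmap a [GeneticMap] covering all SNPs.
#' @param seed integer RNG seed.
#' @return A [HaplotypeSet] for every animal in the pedigree.
#' @export
geneDrop <- function(ped, founderHaps, gmap, seed = 1L) {
  stopifnot(is(ped, "Pedigree"), is(founderHaps, "HaplotypeSet"),
            is(gmap, "GeneticMap"))
  set.seed(seed)
  snps <- gmap@map$snp
  nS <- length(snps)
  if (!identical(dimnames(founderHaps@alleles)[[1]], snps))
    stop("founder haplotypes do not match the map SNP frame")
  founders <- ped@id[is.na(ped@sire) & is.na(ped@dam)]
  missingF <- setdiff(founders, dimnames(founderHaps@alleles)[[3]])
  if (length(missingF))
    stop("missing founder haplotypes for: ", paste(head(missingF, 5), collapse = ", "))
  ord <- order(ped@year)
  a <- array(0L, dim = c(nS, 2L, length(ped@id)),
             dimnames = list(snps, NULL, ped@id))
  a[, , founders] <- founderHaps@alleles[, , founders]
  chroms <- unique(gmap@map$chrom)
  chromIdx <- lapply(chroms, function(ch) which(gmap@map$chrom == ch))
  names(chromIdx) <- chroms
  for (i in ord) {
    if (is.na(ped@sire[i])) next
    for (side in 1:2) {
      parent <- if (side == 1L) ped@sire[i] else ped@dam[i]
      gam <- integer(nS)
      for (ch in chroms) {
        idx <- chromIdx[[ch]]
        gam[idx] <- .dropGamete(a[idx, , parent], gmap@map$pos[idx],
                                gmap@morgans[[ch]])
      }
      a[, side, ped@id[i]] <- gam
    }
  }
  HaplotypeSet(a)
}

#' Add genotyping error and missingness
#'
#' Perturbs each called entry independently: with probability `errorRate`
#' the dosage is replaced by one of the two other dosage values (uniformly),
#' then with probability `missingRate` the entry is set to missing.  The
#' input object is not modified.
#'
#' @param gd a [GenotypeData].
#' @param errorRate,missingRate proportions in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return A new [GenotypeData].
#' @export
addGenotypeNoise <- function(gd, errorRate = 0, missingRate = 0, seed = 1L) {
  stopifnot(is(gd, "GenotypeData"))
  if (errorRate < 0 || errorRate > 1 || missingRate < 0 || missingRate > 1)
    stop("rates must be in [0, 1]")
  d <- dosages(gd)
  set.seed(seed)
  if (errorRate > 0) {
    called <- which(!is.na(d))
    flip <- called[runif(length(called)) < errorRate]
    if (length(flip)) {
      old <- d[flip]
      pick <- ifelse(runif(length(flip)) < 0.5, 1L, 2L)
      ## the two wrong states, in increasing order, per entry
      wrong1 <- ifelse(old == 0L, 1L, 0L)
      wrong2 <- ifelse(old == 2L, 1L, 2L)
      d[flip] <- ifelse(pick == 1L, wrong1, wrong2)
    }
  }
  if (missingRate > 0) {
    drop <- which(runif(length(d)) < missingRate)
    d[drop] <- NA_integer_
  }
  GenotypeData(d, markerMapFrame(gd))
}

#' Simulate a complete population
#'
#' Convenience wrapper chaining [simulateFounderFrequencies()],
#' [simulatePedigree()], [simulateFounderHaplotypes()], [geneDrop()] and
#' [addGenotypeNoise()].  Sub-seeds are derived deterministically from
#' `seed`.
#'
#' @param plan a [BreedPlan] (default [defaultBreedPlan()]).
#' @param gmap a [GeneticMap] (default [defaultGeneticMap()]).
#' @param seed integer RNG seed.
#' @param errorRate,missingRate genotype noise rates.
#' @return list with elements `genotypes` ([GenotypeData], after noise),
#'   `truth` (noise-free [GenotypeData]), `pedigree`, `haplotypes`,
#'   `frequencies` (SNPs x breeds) and `map` (the [GeneticMap]).
#' @export
simulatePopulation <- function(plan = defaultBreedPlan(),
                               gmap = defaultGeneticMap(), seed = 1L,
                               errorRate = 0, missingRate = 0) {
  nS <- nrow(gmap@map)
  freqs <- simulateFounderFrequencies(nS, plan, seed = seed)
  ped <- simulatePedigree(plan, seed = seed + 1L)
  fh <- simulateFounderHaplotypes(ped, freqs, gmap, seed = seed + 2L)
  haps <- geneDrop(ped, fh, gmap, seed = seed + 3L)
  truth <- haplotypesToGenotypes(haps, asMarkerMap(gmap))
  geno <- if (errorRate > 0 || missingRate > 0)
    addGenotypeNoise(truth, errorRate, missingRate, seed = seed + 4L) else truth
  list(genotypes = geno, truth = truth, pedigree = ped, haplotypes = haps,
       frequencies = freqs, map = gmap)
}
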