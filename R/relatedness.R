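#' Allele frequencies over a stated animal set
#'
#' B-allele frequency per SNP, `p = sum(dosage) / (2 * called)`, computed
#' from non-missing genotypes only.  SNPs with zero calls get `NA` and are
#' flagged (attribute `"noCalls"`); downstream scaling sums skip them.
#'
#' @param gd a [GenotypeData].
#' @param animals animal ids to compute over (default: all).
#' @return named numeric vector of frequencies with attribute `noCalls`.
#' @export
alleleFrequencies <- function(gd, animals = NULL) {
  stopifnot(is(gd, "GenotypeData"))
  d <- dosages(gd)
  if (!is.null(animals)) {
    if (!length(animals)) stop("animal set must be non-empty")
    d <- d[, colnames(d) %in% animals, drop = FALSE]
    if (ncol(d) != length(unique(animals))) stop("unknown animals in set")
  }
  called <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * pmax(called, 1L))
  p[called == 0] <- NA_real_
  structure(setNames(p, rownames(d)), noCalls = rownames(d)[called == 0])
}

#' VanRaden genomic relationship matrix
#'
#' Computes `G = X X' / (2 * sum(p_i (1 - p_i)))` where `X` is the
#' 2p-centered dosage incidence matrix (animals x SNPs, entry
#' `dosage - 2 p_i`; missing dosages contribute 0 after centering, i.e.
#' mean imputation) and the denominator is VanRaden's method-1 scaling.
#' SNPs with undefined frequency are excluded; monomorphic SNPs contribute
#' nothing to the scaling sum, and an all-monomorphic input is an error.
#'
#' @param gd a [GenotypeData].
#' @param freqs allele frequencies from [alleleFrequencies()]; defaults to
#'   frequencies over all animals in `gd`.
#' @param animals animals to include in G (default: all in `gd`).
#' @return A [GRM].
#' @export
computeG <- function(gd, freqs = NULL, animals = NULL) {
  stopifnot(is(gd, "GenotypeData"))
  d <- dosages(gd)
  if (!is.null(animals)) d <- d[, colnames(d) %in% animals, drop = FALSE]
  if (ncol(d) < 2) stop("G needs at least two animals")
  if (is.null(freqs)) freqs <- alleleFrequencies(gd, animals)
  freqs <- freqs[rownames(d)]
  ok <- !is.na(freqs)
  p <- freqs[ok]
  scale <- 2 * sum(p * (1 - p))
  if (scale <= 0) stop("degenerate scaling: all SNPs monomorphic")
  X <- t(d[ok, , drop = FALSE]) - matrix(2 * p, ncol(d), sum(ok), byrow = TRUE)
  X[is.na(X)] <- 0
  dimnames(X) <- list(colnames(d), rownames(d)[ok])
  G <- tcrossprod(X) / scale
  new("GRM", G = G, X = X, freqs = p, scale = scale)
}

#' Top-k genomic relationships of target animals to a reference set
#'
#' For each target, the k largest G entries against the reference animals
#' (descending; ties broken by reference id order).  If the reference holds
#' fewer than k animals all are used and the shortfall is recorded.  The
#' scenario-level summary reports the mean over targets of the per-target
#' top-k mean (the "Mean Top10" convention), and likewise the means of the
#' per-target minima and maxima.
#'
#' @param grm a [GRM] covering reference and targets.
#' @param reference,targets disjoint animal id vectors.
#' @param k number of most related reference animals (default 10).
#' @return list with `perTarget` (data.frame target/rank/reference/
#'   relationship), `summary` (per-target mean/min/max), `scenario`
#'   (meanTop, minTop, maxTop), `k` and `shortfall`.
#' @export
topKRelationships <- function(grm, reference, targets, k = 10L) {
  stopifnot(is(grm, "GRM"), k >= 1)
  k <- as.integer(k)
  if (!length(reference)) stop("empty reference set")
  if (length(intersect(reference, targets)))
    stop("reference and targets must be disjoint")
  G <- grm@G
  reference <- sort(reference)
  kUse <- min(k, length(reference))
  rows <- lapply(targets, function(t) {
    g <- G[t, reference]
    ord <- order(-g, seq_along(g))[seq_len(kUse)]
    data.frame(target = t, rank = seq_len(kUse), reference = reference[ord],
               relationship = unname(g[ord]), stringsAsFactors = FALSE)
  })
  perTarget <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(perTarget$relationship, perTarget$target),
                                function(v) data.frame(mean = mean(v), min = min(v),
                                                       max = max(v))))
  summ <- data.frame(target = rownames(summ), summ, row.names = NULL,
                     stringsAsFactors = FALSE)
  summ <- summ[match(targets, summ$target), ]
  list(perTarget = perTarget, summary = summ,
       scenario = c(meanTop = mean(summ$mean), minTop = mean(summ$min),
                    maxTop = mean(summ$max)),
       k = kUse, shortfall = max(0L, k - length(reference)))
}

#' Opposing-homozygote count between two animals
#'
#' Mendelian inconsistency (MI) between two genotype vectors: the number
#' of SNPs at which one animal is AA (0) and the other BB (2).  SNPs with
#' a missing call in either animal are excluded from both the count and
#' the co-called total.  MI is symmetric and unaffected by a consistent
#' A/B relabeling at any SNP.
#'
#' @param a,b integer dosage vectors on the same SNP frame.
#' @return list with `count` and `coCalled`.
#' @export
mendelianInconsistency <- function(a, b) {
  if (length(a) != length(b)) stop("genotype vectors must share a SNP frame")
  both <- !is.na(a) & !is.na(b)
  list(count = sum((a[both] == 0L & b[both] == 2L) |
                     (a[both] == 2L & b[both] == 0L)),
       coCalled = sum(both))
}

## MI counts for all target x reference pairs, via indicator cross-products.
.miMatrix <- function(d, targets, reference) {
  Tm <- d[, targets, drop = FALSE]
  Rm <- d[, reference, drop = FALSE]
  t0 <- !is.na(Tm) & Tm == 0L; t2 <- !is.na(Tm) & Tm == 2L
  r0 <- !is.na(Rm) & Rm == 0L; r2 <- !is.na(Rm) & Rm == 2L
  mi <- crossprod(t0, r2) + crossprod(t2, r0)
  co <- crossprod(!is.na(Tm) * 1, !is.na(Rm) * 1)
  list(mi = mi, coCalled = co)
}

#' Pairwise Mendelian-inconsistency profile
#'
#' MI and co-called counts for every target x reference pair.
#'
#' @param gd a [GenotypeData].
#' @param targets,reference animal id vectors.
#' @return data.frame with columns target, reference, mi, coCalled.
#' @export
miProfile <- function(gd, targets, reference) {
  stopifnot(is(gd, "GenotypeData"))
  if (!length(reference)) stop("empty reference set")
  m <- .miMatrix(dosages(gd), targets, reference)
  data.frame(target = rep(targets, times = length(reference)),
             reference = rep(reference, each = length(targets)),
             mi = as.vector(m$mi), coCalled = as.vector(m$coCalled),
             stringsAsFactors = FALSE)
}

#' Average MI over the k best-matching reference animals (AVTOP10)
#'
#' For each target, averages the Mendelian-inconsistency counts over k
#' reference animals.  By default (`rankBy = "mi"`) these are the k
#' reference animals with the lowest MI against the target, ties broken by
#' ascending reference id; with `rankBy = "relationship"` they are the k
#' most G-related reference animals (requires `grm`).  Both conventions
#' appear in field practice for relating pre-imputation MI profiles to
#' later imputation accuracy; the lowest-MI form is the default and the
#' two rank targets concordantly on related data.
#'
#' @param gd a [GenotypeData] (typically at the low panel density).
#' @param targets,reference animal id vectors; reference must be non-empty.
#' @param k number of reference animals averaged (default 10).
#' @param rankBy `"mi"` or `"relationship"`.
#' @param grm a [GRM], required for `rankBy = "relationship"`.
#' @return data.frame with columns `target`, `avTopMI`, `kUsed`.
#' @export
avTopMI <- function(gd, targets, reference, k = 10L,
                    rankBy = c("mi", "relationship"), grm = NULL) {
  rankBy <- match.arg(rankBy)
  stopifnot(is(gd, "GenotypeData"))
  if (!length(reference)) stop("empty reference set")
  reference <- sort(reference)
  m <- .miMatrix(dosages(gd), targets, reference)
  kUse <- min(as.integer(k), length(reference))
  av <- vapply(seq_along(targets), function(i) {
    mi <- m$mi[i, ]
    ord <- if (rankBy == "mi") order(mi, reference)
           else {
             if (is.null(grm)) stop("rankBy = 'relationship' needs a GRM")
             order(-grm@G[targets[i], reference], reference)
           }
    mean(mi[ord[seq_len(kUse)]])
  }, numeric(1))
  data.frame(target = targets, avTopMI = av, kUsed = kUse,
             stringsAsFactors = FALSE)
}
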