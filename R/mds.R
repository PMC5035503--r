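#' MDS clustering of animals from genomic relationships
#'
#' Classical (Torgerson) multidimensional scaling of the genomic distances
#' `d_ij = sqrt(g_ii + g_jj - 2 g_ij)` derived from a genomic relationship
#' matrix, after sampling up to `samplePerGroup` animals per breed/group.
#' Negative eigenvalues (the distance matrix need not be Euclidean under
#' missingness) are truncated by `cmdscale` and their number recorded.
#'
#' @param grm a [GRM].
#' @param groups named character vector mapping animal id to breed/group
#'   label; only animals named here are eligible.
#' @param samplePerGroup animals sampled per group (all if fewer).
#' @param dims number of MDS dimensions (default 2).
#' @param seed integer seed for the per-group sampling.
#' @return data.frame with columns `animal`, `group` and `MDS1..MDSd`,
#'   with attribute `negativeEigenvalues`.
#' @export
mdsCluster <- function(grm, groups, samplePerGroup = 100L, dims = 2L,
                       seed = 1L) {
  stopifnot(is(grm, "GRM"), dims >= 1)
  ids <- intersect(rownames(grm@G), names(groups))
  if (!length(ids)) stop("no animals in common between GRM and groups")
  set.seed(seed)
  chosen <- unlist(lapply(split(ids, groups[ids]), function(v) {
    if (length(v) <= samplePerGroup) v
    else sample(v, samplePerGroup)
  }), use.names = FALSE)
  G <- grm@G[chosen, chosen]
  dg <- diag(G)
  D2 <- outer(dg, dg, "+") - 2 * G
  D2[D2 < 0] <- 0   # numerical guard
  fit <- cmdscale(sqrt(D2), k = dims, eig = TRUE)
  coords <- fit$points
  colnames(coords) <- paste0("MDS", seq_len(dims))
  out <- data.frame(animal = chosen, group = unname(groups[chosen]),
                    coords, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "negativeEigenvalues") <- sum(fit$eig < -1e-8)
  out
}
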