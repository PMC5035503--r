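## Independent brute-force oracles, kept deliberately naive (double loops,
## direct formulas) so they share no code path with the implementation.

bruteG <- function(d, p) {
  ok <- !is.na(p)
  d <- d[ok, , drop = FALSE]; p <- p[ok]
  scale <- 2 * sum(p * (1 - p))
  n <- ncol(d)
  G <- matrix(0, n, n, dimnames = list(colnames(d), colnames(d)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(nrow(d))) {
      xi <- if (is.na(d[k, i])) 0 else d[k, i] - 2 * p[k]
      xj <- if (is.na(d[k, j])) 0 else d[k, j] - 2 * p[k]
      s <- s + xi * xj
    }
    G[i, j] <- s / scale
  }
  G
}

bruteFreq <- function(d) {
  apply(d, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else sum(v) / (2 * length(v))
  })
}

bruteMI <- function(a, b) {
  count <- 0L; co <- 0L
  for (k in seq_along(a)) {
    if (is.na(a[k]) || is.na(b[k])) next
    co <- co + 1L
    if ((a[k] == 0 && b[k] == 2) || (a[k] == 2 && b[k] == 0)) count <- count + 1L
  }
  c(count = count, coCalled = co)
}

bruteCR <- function(tv, iv) {
  ok <- !is.na(tv) & !is.na(iv)
  if (!sum(ok)) return(NA_real_)
  100 * sum(tv[ok] == iv[ok]) / sum(ok)
}

bruteR2 <- function(tv, iv) {
  ok <- !is.na(tv) & !is.na(iv)
  if (sum(ok) < 2) return(NA_real_)
  x <- tv[ok]; y <- iv[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

## Random GenotypeData on a simple one-chromosome map.
randomGenotypeData <- function(nSnp, nAnimal, missRate = 0, seed = 1) {
  set.seed(seed)
  d <- matrix(sample(0:2, nSnp * nAnimal, replace = TRUE), nSnp, nAnimal)
  if (missRate > 0) d[runif(length(d)) < missRate] <- NA_integer_
  dimnames(d) <- list(sprintf("s%04d", seq_len(nSnp)),
                      sprintf("a%03d", seq_len(nAnimal)))
  map <- data.frame(chrom = "1", pos = seq_len(nSnp) * 100L,
                    alleleA = "A", alleleB = "B",
                    row.names = rownames(d), stringsAsFactors = FALSE)
  GenotypeData(d, map)
}

## Forge a GRM directly from a Gram matrix (for geometry tests).
forgeGRM <- function(G) {
  methods::new("GRM", G = G, X = matrix(0, nrow(G), 1), freqs = 0.5, scale = 1)
}
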