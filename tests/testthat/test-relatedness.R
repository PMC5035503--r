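test_that("allele frequencies use non-missing calls only", {
  d <- rbind(s1 = c(0L, 1L, 2L), s2 = c(2L, 2L, 2L), s3 = c(2L, NA, 1L),
             s4 = c(NA_integer_, NA, NA))
  colnames(d) <- c("a", "b", "c")
  gd <- GenotypeData(d, data.frame(chrom = "1", pos = 1:4 * 10L, alleleA = "A",
                                   alleleB = "B", row.names = rownames(d)))
  p <- alleleFrequencies(gd)
  expect_equal(unname(p[c("s1", "s2", "s3")]), c(0.5, 1, 0.75))
  expect_true(is.na(p["s4"]))
  expect_identical(attr(p, "noCalls"), "s4")
  expect_error(alleleFrequencies(gd, character(0)), "non-empty")
})

test_that("G reproduces the hand-derived single-SNP case", {
  d <- matrix(c(0L, 2L), 1, 2, dimnames = list("s1", c("a", "b")))
  gd <- GenotypeData(d, data.frame(chrom = "1", pos = 10L, alleleA = "A",
                                   alleleB = "B", row.names = "s1"))
  g <- computeG(gd, freqs = c(s1 = 0.5))
  expect_equal(relMatrix(g), matrix(c(2, -2, -2, 2), 2,
                                    dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(g@scale, 0.5)
})

test_that("G matches the brute-force oracle and duplicates share rows", {
  for (seed in 1:20) {
    gd <- randomGenotypeData(sample(10:100, 1), sample(3:10, 1),
                             missRate = 0.1, seed = seed)
    p <- alleleFrequencies(gd)
    expect_equal(relMatrix(computeG(gd, p)), bruteG(dosages(gd), p),
                 tolerance = 1e-10)
  }
  gd <- randomGenotypeData(50, 6, seed = 3)
  d <- dosages(gd)
  d <- cbind(d, dup = d[, 1])
  gd2 <- GenotypeData(d, data.frame(chrom = "1", pos = seq_len(50) * 100L,
                                    alleleA = "A", alleleB = "B",
                                    row.names = rownames(d)))
  G <- relMatrix(computeG(gd2))
  expect_equal(unname(G[, 1]), unname(G[, "dup"]))

  mono <- GenotypeData(matrix(2L, 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b"))),
                       data.frame(chrom = "1", pos = 1:3 * 10L, alleleA = "A",
                                  alleleB = "B", row.names = paste0("s", 1:3)))
  expect_error(computeG(mono), "monomorphic")
})

test_that("top-k relationships rank by G with shortfall recording", {
  gd <- randomGenotypeData(80, 8, seed = 12)
  d <- dosages(gd)
  d <- cbind(d, copy = d[, "a001"])
  gd2 <- GenotypeData(d, data.frame(chrom = "1", pos = seq_len(80) * 100L,
                                    alleleA = "A", alleleB = "B",
                                    row.names = rownames(d)))
  grm <- computeG(gd2)
  tk <- topKRelationships(grm, reference = "copy", targets = "a001", k = 1)
  expect_equal(tk$perTarget$relationship, relMatrix(grm)["a001", "a001"])

  tk2 <- topKRelationships(grm, reference = colnames(d)[2:6],
                           targets = "a001", k = 10)
  expect_identical(tk2$k, 5L)
  expect_identical(tk2$shortfall, 5L)
  expect_true(all(diff(tk2$perTarget$relationship) <= 0))
  expect_error(topKRelationships(grm, character(0), "a001"), "empty")
  expect_error(topKRelationships(grm, "a001", "a001"), "disjoint")
})

test_that("Mendelian inconsistency counts opposing homozygotes symmetrically", {
  expect_identical(mendelianInconsistency(c(0L, 2L, 1L), c(0L, 2L, 1L))$count, 0L)
  r <- mendelianInconsistency(c(0L, 2L, 1L), c(2L, 2L, 1L))
  expect_identical(r$count, 1L); expect_identical(r$coCalled, 3L)
  r2 <- mendelianInconsistency(c(0L, NA), c(2L, 2L))
  expect_identical(r2$count, 1L); expect_identical(r2$coCalled, 1L)

  for (seed in 1:25) {
    set.seed(seed)
    a <- sample(c(0:2, NA), 40, TRUE); b <- sample(c(0:2, NA), 40, TRUE)
    ab <- mendelianInconsistency(a, b)
    expect_identical(ab$count, mendelianInconsistency(b, a)$count)
    expect_identical(unname(bruteMI(a, b)["count"]), ab$count)
    expect_identical(unname(bruteMI(a, b)["coCalled"]), ab$coCalled)
    ## consistent A/B relabeling at every SNP leaves MI unchanged
    expect_identical(mendelianInconsistency(2L - a, 2L - b)$count, ab$count)
  }
})

test_that("AVTOP10 averages the lowest-MI reference animals", {
  nS <- 10L
  mk <- function(v) matrix(v, nS, 1)
  d <- cbind(tgt = rep(0L, nS),
             r1 = c(2L, rep(0L, 9)), r2 = c(2L, 2L, rep(0L, 8)),
             r3 = c(rep(2L, 3), rep(0L, 7)), r4 = c(rep(2L, 4), rep(0L, 6)))
  rownames(d) <- sprintf("s%02d", 1:nS)
  gd <- GenotypeData(d, data.frame(chrom = "1", pos = 1:nS * 10L, alleleA = "A",
                                   alleleB = "B", row.names = rownames(d)))
  av <- avTopMI(gd, "tgt", c("r1", "r2", "r3", "r4"), k = 2)
  expect_equal(av$avTopMI, 1.5)

  dup <- cbind(tgt = rep(1L, nS), c1 = rep(1L, nS), c2 = rep(1L, nS))
  rownames(dup) <- rownames(d)
  gdd <- GenotypeData(dup, data.frame(chrom = "1", pos = 1:nS * 10L, alleleA = "A",
                                      alleleB = "B", row.names = rownames(d)))
  expect_equal(avTopMI(gdd, "tgt", c("c1", "c2"), k = 2)$avTopMI, 0)
  expect_error(avTopMI(gd, "tgt", character(0)), "empty")
})

test_that("offspring with parents in the reference have the lowest AVTOP10", {
  w <- worldMulti()
  tab <- w$tab
  gdLow <- maskToPanel(w$pop$truth, w$panels[[1]])
  offspring <- w$romTargets[1:10]
  unrelated <- w$termTargets[1:10]
  av <- avTopMI(gdLow, c(offspring, unrelated), w$romRefs, k = 10)
  expect_lt(mean(av$avTopMI[1:10]), mean(av$avTopMI[11:20]))
})

test_that("classical MDS recovers planar geometry from G-derived distances", {
  ## Gram matrix of points (0,0), (3,0), (0,4): pairwise distances 3, 4, 5
  P <- rbind(o = c(0, 0), x = c(3, 0), y = c(0, 4))
  grm <- forgeGRM(P %*% t(P))
  out <- mdsCluster(grm, groups = setNames(rep("g", 3), rownames(P)),
                    samplePerGroup = 3, dims = 2, seed = 1)
  coords <- as.matrix(out[, c("MDS1", "MDS2")])
  expect_equal(as.vector(dist(coords)), c(3, 4, 5), tolerance = 1e-8)

  ## identical animals land on identical coordinates
  G2 <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  out2 <- mdsCluster(forgeGRM(G2), groups = setNames(rep("g", 3), c("a", "b", "c")),
                     samplePerGroup = 3, seed = 1)
  ca <- unlist(out2[out2$animal == "a", c("MDS1", "MDS2")])
  cb <- unlist(out2[out2$animal == "b", c("MDS1", "MDS2")])
  expect_equal(ca, cb, ignore_attr = TRUE)
})

test_that("high-divergence breeds separate in MDS space", {
  plan <- BreedPlan(breeds = c("b1", "b2"), divergence = c(b1 = 0.3, b2 = 0.3),
                    founders = c(b1 = 25L, b2 = 25L), matings = list())
  pop <- simulatePopulation(plan, defaultGeneticMap(2L, 250L), seed = 66)
  grm <- computeG(pop$truth)
  groups <- setNames(ifelse(grepl("^b1", animalIds(pop$truth)), "b1", "b2"),
                     animalIds(pop$truth))
  out <- mdsCluster(grm, groups, samplePerGroup = 25, seed = 2)
  xy <- as.matrix(out[, c("MDS1", "MDS2")])
  cent <- rbind(colMeans(xy[out$group == "b1", ]), colMeans(xy[out$group == "b2", ]))
  between <- sqrt(sum((cent[1, ] - cent[2, ])^2))
  within <- mean(c(dist(xy[out$group == "b1", ]), dist(xy[out$group == "b2", ])))
  expect_gt(between, within)
})
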