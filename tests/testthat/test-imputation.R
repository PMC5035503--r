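.frame <- function(d) {
  GenotypeData(d, data.frame(chrom = "1", pos = seq_len(nrow(d)) * 100L,
                             alleleA = "A", alleleB = "B",
                             row.names = rownames(d)))
}

test_that("major-allele baseline fills by allele frequency with het ties", {
  d <- matrix(NA_integer_, 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b")))
  d[3, 1] <- 1L
  gd <- .frame(d)
  res <- imputeMajorAllele(gd, c(s1 = 0.9, s2 = 0.1, s3 = 0.5))
  out <- dosages(res)
  expect_identical(unname(out["s1", ]), c(2L, 2L))
  expect_identical(unname(out["s2", ]), c(0L, 0L))
  expect_identical(unname(out["s3", ]), c(1L, 1L))   # observed 1 passes through
  expect_false(imputedMask(res)["s3", "a"])
  expect_error(imputeMajorAllele(gd, c(s1 = 0.9, s2 = NA, s3 = 0.5)),
               "undefined")
})

test_that("window imputer recovers a target identical to one reference animal", {
  set.seed(13)
  nS <- 24L
  low <- sprintf("s%02d", seq(1, nS, by = 4))
  snps <- sprintf("s%02d", 1:nS)
  ## references differ at every low SNP so matching is unambiguous
  r1 <- rep(c(0L, 1L), nS / 2); r2 <- rep(c(2L, 1L), nS / 2)
  r3 <- rep(c(1L, 0L), nS / 2)
  R <- cbind(r1 = r1, r2 = r2, r3 = r3); rownames(R) <- snps
  ref <- .frame(R)
  tgt <- matrix(NA_integer_, nS, 1, dimnames = list(snps, "t"))
  tgt[low, 1] <- R[low, "r2"]
  res <- imputeWindowHaplotype(.frame(tgt), ref, low, snps,
                               window = 8, overlap = 4)
  expect_identical(unname(dosages(res)[, "t"]), unname(R[, "r2"]))
  ## with truth equal to that reference, concordance is 100%
  truthR2 <- R[, "r2", drop = FALSE]
  colnames(truthR2) <- "t"
  expect_equal(as.numeric(concordanceRate(.frame(truthR2),
                                          imputedGenotypes(res), "animal")), 100)
})

test_that("a single reference animal fills every target with its genotypes", {
  gd <- randomGenotypeData(30, 4, seed = 5)
  low <- snpIds(gd)[seq(1, 30, by = 5)]
  masked <- maskToPanel(gd, PanelDef("low", low))
  ref <- randomGenotypeData(30, 1, seed = 6)
  res <- imputeWindowHaplotype(masked, ref, low, snpIds(gd),
                               window = 10, overlap = 2)
  filled <- dosages(res)
  one <- dosages(ref)[, 1]
  for (j in seq_len(ncol(filled))) {
    m <- imputedMask(res)[, j]
    expect_identical(filled[m, j], one[m])
  }
  expect_error(imputeWindowHaplotype(masked, subsetGenotypes(ref, character(0)),
                                     low, snpIds(gd)), "empty reference")
  expect_error(imputeWindowHaplotype(masked, ref, low, snpIds(gd), window = 1),
               "window")
})

test_that("window imputation is deterministic and never alters observed calls", {
  w <- worldMulti()
  truth <- subsetGenotypes(w$pop$truth, animals = w$romTargets)
  masked <- maskToPanel(truth, w$panels[[1]])
  ref <- subsetGenotypes(w$pop$truth, animals = w$romRefs)
  r1 <- imputeWindowHaplotype(masked, ref, w$panels[[1]], w$panels[[3]],
                              window = 100, overlap = 50)
  r2 <- imputeWindowHaplotype(masked, ref, w$panels[[1]], w$panels[[3]],
                              window = 100, overlap = 50)
  expect_identical(dosages(r1), dosages(r2))
  obs <- !is.na(dosages(masked))
  expect_identical(dosages(r1)[obs], dosages(masked)[obs])
  expect_false(anyNA(dosages(r1)[snpIds(truth) %in% panelSnps(w$panels[[3]]), ]))

  resM <- imputeMajorAllele(masked, alleleFrequencies(ref))
  expect_identical(dosages(resM)[obs], dosages(masked)[obs])
})

test_that("two-step with a degenerate middle panel equals one-step", {
  w <- worldMulti()
  truth <- subsetGenotypes(w$pop$truth, animals = w$romTargets[1:10])
  masked <- maskToPanel(truth, w$panels[[1]])
  ref <- subsetGenotypes(w$pop$truth, animals = w$romRefs[1:80])
  one <- imputeWindowHaplotype(masked, ref, w$panels[[1]], w$panels[[3]],
                               window = 100, overlap = 50)
  midHigh <- imputeTwoStep(masked, ref, ref,
                           list(w$panels[[1]], w$panels[[3]], w$panels[[3]]),
                           window = 100, overlap = 50)
  expect_identical(dosages(midHigh), dosages(one))
  midLow <- imputeTwoStep(masked, ref, ref,
                          list(w$panels[[1]], w$panels[[1]], w$panels[[3]]),
                          window = 100, overlap = 50)
  expect_identical(dosages(midLow), dosages(one))
  expect_length(midHigh@trace, 2L)
  expect_error(imputeTwoStep(masked, ref, ref,
                             list(w$panels[[2]], w$panels[[1]], w$panels[[3]])),
               "nested")
})

test_that("external-format export/import round-trips including missing codes", {
  gd <- randomGenotypeData(25, 6, seed = 9)
  low <- snpIds(gd)[seq(1, 25, by = 5)]
  masked <- maskToPanel(subsetGenotypes(gd, animals = c("a001", "a002")),
                        PanelDef("low", low))
  ref <- subsetGenotypes(gd, animals = c("a003", "a004", "a005", "a006"))
  for (fmt in c("fimpute_dialect", "beagle3_dialect")) {
    dir <- withr::local_tempdir()
    exportExternal(masked, ref, fmt, dir)
    back <- importExternal(dir, masked, fmt)
    expect_identical(dosages(back), dosages(masked))
  }
  ## fimpute dialect: distinct chip indices and "5" as the missing symbol
  dir <- withr::local_tempdir()
  exportExternal(masked, ref, "fimpute_dialect", dir)
  lines <- readLines(file.path(dir, "genotypes.txt"))[-1]
  chips <- vapply(strsplit(lines, " "), `[[`, "", 2)
  expect_setequal(unique(chips), c("1", "2"))
  tgtLine <- strsplit(lines[grepl("^a001 ", lines)], " ")[[1]][3]
  expect_true(grepl("5", tgtLine))
  expect_error(exportExternal(masked, ref, "parquet", dir))
})

test_that("window imputation beats the chance baseline for related references", {
  w <- worldScenario()
  sc <- Scenario("win", w$refs, w$targets, w$panels[[1]], w$panels[[3]])
  scM <- Scenario("maj", w$refs, w$targets, w$panels[[1]], w$panels[[3]],
                  method = list(name = "major"))
  crW <- runScenario(sc, w$pop$truth)$overall["cr"]
  crM <- runScenario(scM, w$pop$truth)$overall["cr"]
  expect_gt(crW, crM)
})
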