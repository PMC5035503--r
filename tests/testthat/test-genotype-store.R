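test_that("VCF and PLINK round trips preserve dosage, missingness, ids and map", {
  gd <- randomGenotypeData(100, 50, missRate = 0.05, seed = 21)
  tmp <- withr::local_tempdir()

  vcf <- file.path(tmp, "g.vcf")
  writeGenotypes(gd, vcf, "vcf")
  back <- readGenotypes(vcf, "vcf")
  expect_identical(dosages(back), dosages(gd))
  expect_identical(markerMap(back), markerMap(gd))

  writeGenotypes(gd, file.path(tmp, "g"), "plink_text")
  backP <- readGenotypes(file.path(tmp, "g"), "plink_text")
  expect_identical(dosages(backP), dosages(gd))
  expect_identical(markerMap(backP), markerMap(gd))
})

test_that("VCF GT values map to dosages with REF as the A allele", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "x1", "x2", "x3", sep = "\t"),
               paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
                     "0/0", "0/1", "1/1", sep = "\t"),
               paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
                     "./.", "0|1", "1/1", sep = "\t")), tmp)
  gd <- readGenotypes(tmp, "vcf")
  expect_identical(unname(dosages(gd)["rs1", ]), c(0L, 1L, 2L))
  expect_identical(unname(dosages(gd)["rs2", ]), c(NA_integer_, 1L, 2L))
  expect_identical(markerMap(gd)$alleleA, c("A", "C"))
})

test_that("PLINK missing code and malformed records are handled", {
  tmp <- withr::local_tempdir()
  writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t200"), file.path(tmp, "p.map"))
  writeLines(c("F 1 0 0 0 -9 A A 0 0",
               "F 2 0 0 0 -9 A G G G"), file.path(tmp, "p.ped"))
  gd <- readGenotypes(file.path(tmp, "p"), "plink_text")
  expect_identical(unname(dosages(gd)[, "1"]), c(0L, NA_integer_))
  ## 4-column map: the first listed allele per SNP is the A allele, so the
  ## G/G genotype at rs2 (whose first non-missing call lists G) codes as 0
  expect_identical(unname(dosages(gd)[, "2"]), c(1L, 0L))

  writeLines(c("F 1 0 0 0 -9 A A"), file.path(tmp, "p.ped"))
  expect_error(readGenotypes(file.path(tmp, "p"), "plink_text"), "line 1")

  writeLines(c("1\trs1\t0\t100", "1\trs1\t0\t200"), file.path(tmp, "q.map"))
  writeLines("F 1 0 0 0 -9 A A A A", file.path(tmp, "q.ped"))
  expect_error(readGenotypes(file.path(tmp, "q"), "plink_text"), "duplicated")
})

test_that("QC filters apply in order with first-failing reasons", {
  ## 100 animals, one SNP heterozygous in all of them: genotype counts
  ## (0, 100, 0) against HWE expectation (25, 50, 25) give chi-square 100
  set.seed(61)
  n <- 100L
  d <- rbind(
    het100 = rep(1L, n),
    lowcall = c(rep(NA_integer_, 6), sample(0:2, n - 6, TRUE)),
    nopos = sample(0:2, n, TRUE),
    good = rbinom(n, 2L, 0.4))
  colnames(d) <- sprintf("a%04d", seq_len(n))
  map <- data.frame(chrom = "1", pos = c(100L, 300L, NA_integer_, 500L),
                    alleleA = "A", alleleB = "B",
                    row.names = rownames(d), stringsAsFactors = FALSE)
  gd <- GenotypeData(d, map)
  res <- qcFilter(gd)
  rep <- res$report$snps
  expect_identical(rep$reason[rep$snp == "lowcall"], "call_rate")
  expect_identical(rep$reason[rep$snp == "nopos"], "position")
  expect_identical(rep$reason[rep$snp == "het100"], "HWE")
  hweP <- rep$hweP[rep$snp == "het100"]
  expect_equal(hweP, pchisq(100, 1, lower.tail = FALSE))
  expect_lt(hweP, 1e-5)
  expect_identical(snpIds(res$genotypes), "good")

  ## MAF below 0.0005 needs a larger animal set: one het among 1250
  n2 <- 1250L
  d2 <- rbind(rare = c(1L, rep(0L, n2 - 1L)), good = rbinom(n2, 2L, 0.4))
  colnames(d2) <- sprintf("b%04d", seq_len(n2))
  gd2 <- GenotypeData(d2, data.frame(chrom = "1", pos = c(10L, 20L),
                                     alleleA = "A", alleleB = "B",
                                     row.names = rownames(d2)))
  res2 <- qcFilter(gd2)
  rep2 <- res2$report$snps
  expect_equal(rep2$maf[rep2$snp == "rare"], 0.0004)
  expect_identical(rep2$reason[rep2$snp == "rare"], "MAF")

  off <- qcThresholds(maf = NA, snpCallRate = NA, hwePvalue = NA,
                      animalCallRate = NA, requirePosition = FALSE)
  resOff <- qcFilter(gd, off)
  expect_identical(dosages(resOff$genotypes), dosages(gd))
})

test_that("QC is idempotent and MAF lives in [0, 0.5]", {
  w <- worldMulti()
  noisy <- addGenotypeNoise(w$pop$truth, errorRate = 0.002, missingRate = 0.02,
                            seed = 4)
  pass1 <- qcFilter(noisy)
  pass2 <- qcFilter(pass1$genotypes)
  expect_true(all(pass2$report$snps$kept))
  expect_true(all(pass2$report$animals$kept))
  maf <- pass1$report$snps$maf
  expect_true(all(maf >= 0 & maf <= 0.5, na.rm = TRUE))
})

test_that("exact HWE test agrees with chi-square on clear cases", {
  ## strongly out of equilibrium under both tests
  expect_lt(hweTest(0, 100, 0, "exact"), 1e-5)
  ## in equilibrium: both comfortably non-significant
  expect_gt(hweTest(25, 50, 25, "exact"), 0.5)
  expect_gt(hweTest(25, 50, 25, "chisq"), 0.5)
  expect_identical(hweTest(30, 0, 0), 1)
})

test_that("panels intersect with the map and verify nesting", {
  gd <- randomGenotypeData(20, 5, seed = 31)
  ids <- snpIds(gd)
  p <- buildPanels(gd, list(low = ids[1:10]))
  expect_length(panelSnps(p[[1]]), 10)

  withMissing <- c(ids[1:6], sprintf("zz%d", 1:4))
  p2 <- buildPanels(gd, list(low = withMissing))
  expect_length(panelSnps(p2[[1]]), 6)

  expect_error(buildPanels(gd, list(a = ids[1:5], b = ids[6:10]), nested = TRUE),
               "not nested")
  expect_error(buildPanels(gd, list(low = c("nope1", "nope2"))), "empty")

  nest <- nestedPanels(gd, c(low = 5L, mid = 10L, high = NA))
  expect_true(all(panelSnps(nest[[1]]) %in% panelSnps(nest[[2]])))
  expect_true(all(panelSnps(nest[[2]]) %in% panelSnps(nest[[3]])))
})

test_that("panel masking blanks non-panel SNPs, keeps the frame, and is idempotent", {
  gd <- randomGenotypeData(20, 8, seed = 41)
  all <- PanelDef("all", snpIds(gd))
  expect_identical(dosages(maskToPanel(gd, all)), dosages(gd))

  five <- PanelDef("five", snpIds(gd)[c(1, 5, 9, 13, 17)])
  m <- maskToPanel(gd, five)
  expect_identical(snpIds(m), snpIds(gd))
  blank <- rowSums(!is.na(dosages(m))) == 0
  expect_identical(sum(blank), 15L)
  expect_identical(dosages(maskToPanel(m, five)), dosages(m))
  expect_error(maskToPanel(gd, PanelDef("bad", "missing_snp")), "absent")
})

test_that("pedigree text round-trips", {
  w <- worldMulti()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writePedigree(w$pop$pedigree, tmp)
  back <- readPedigree(tmp)
  expect_identical(pedigreeTable(back), pedigreeTable(w$pop$pedigree))
})
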