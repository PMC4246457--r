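test_that("identical seed and config give byte-identical runs", {
  lay <- exampleLayout(2, 2)
  cfg <- simConfig(lay, list(
    A1 = list(alleles = list(alleleDeletion(5, -2), alleleWildtype()),
              fractions = c(0.5, 0.5), depth = 50L),
    B2 = list(alleles = list(alleleWildtype()), fractions = 1, depth = 30L)))
  s1 <- simulateRun(cfg, seed = 99)
  s2 <- simulateRun(cfg, seed = 99)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateRun(cfg, seed = 100)
  expect_false(identical(s1$reads, s3$reads))
})

test_that("truth tables conserve reads and depths", {
  lay <- exampleLayout(3, 2)
  wells <- enumerateWells(lay)$well
  cfgs <- setNames(lapply(wells, function(w)
    list(alleles = list(alleleWildtype()), fractions = 1)), wells)
  cfg <- simConfig(lay, cfgs, meanDepth = 80, depthSigma = 0.4)
  sim <- simulateRun(cfg, seed = 4)
  expect_equal(length(sim$reads), nrow(sim$truth))
  expect_equal(sum(sim$wells$depth), length(sim$reads))
  expect_equal(anyDuplicated(sim$truth$read_id), 0L)
  byWell <- table(sim$truth$well)
  expect_equal(as.integer(byWell[sim$wells$well]), sim$wells$depth)
})

test_that("emission orientation is an unbiased coin", {
  lay <- exampleLayout(1, 1)
  cfg <- simConfig(lay, list(A1 = list(alleles = list(alleleWildtype()),
                                       fractions = 1, depth = 10000L)),
                   substitutionRate = 0, homopolymerIndelRate = 0,
                   barcodeErrorRate = 0)
  sim <- simulateRun(cfg, seed = 8)
  plusFrac <- mean(sim$truth$orientation == "plus")
  expect_lt(abs(plusFrac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("the realized substitution error rate matches the configured rate", {
  lay <- exampleLayout(1, 1)
  rate <- 0.01
  cfg <- simConfig(lay, list(A1 = list(alleles = list(alleleWildtype()),
                                       fractions = 1, depth = 2000L)),
                   substitutionRate = rate, homopolymerIndelRate = 0,
                   barcodeErrorRate = rate)
  sim <- simulateRun(cfg, seed = 13)
  clean <- paste0(columnBarcodes(lay)[[1]], referenceAmplicon(lay),
                  revComp(rowBarcodes(lay)[[1]]))
  seqs <- ifelse(sim$truth$orientation == "minus", revComp(sim$reads),
                 sim$reads)
  nBases <- nchar(clean) * length(seqs)
  nErr <- sum(vapply(seqs, function(s)
    sum(strsplit(s, "")[[1]] != strsplit(clean, "")[[1]]), 0L))
  expect_lt(abs(nErr / nBases - rate), 3 * sqrt(rate * (1 - rate) / nBases))
})

test_that("a zero-error wildtype well closes the loop through the pipeline", {
  lay <- exampleLayout(2, 1)
  cfg <- simConfig(lay, list(A2 = list(alleles = list(alleleWildtype()),
                                       fractions = 1, depth = 120L)),
                   substitutionRate = 0, homopolymerIndelRate = 0,
                   barcodeErrorRate = 0)
  sim <- simulateRun(cfg, seed = 2)
  expect_equal(length(sim$reads), 120L)
  ## every read reconstructs the clean molecule exactly
  clean <- paste0(columnBarcodes(lay)[[2]], referenceAmplicon(lay),
                  revComp(rowBarcodes(lay)[[1]]))
  seqs <- ifelse(sim$truth$orientation == "minus", revComp(sim$reads), sim$reads)
  expect_true(all(seqs == clean))
  res <- runPipeline(sim$reads, lay)
  expect_equal(res$genotypes$class, "WILDTYPE")
  expect_equal(res$genotypes$well, "A2")
})

test_that("a compound-het well with 1 and 13 nt deletions is recovered exactly", {
  lay <- exampleLayout()
  cfg <- simConfig(lay, list(A6 = list(
    alleles = list(alleleDeletion(1, 0), alleleDeletion(13, -6)),
    fractions = c(0.5, 0.5), depth = 400L)))
  sim <- simulateRun(cfg, seed = 7)
  res <- runPipeline(sim$reads, lay)
  expect_equal(res$genotypes$class, "COMPOUND_HETEROZYGOUS")
  sizes <- sort(res$calls$A6$alleles$signature)
  lens <- sort(as.integer(sub("^D:[0-9]+:", "", sizes)))
  expect_equal(lens, c(1L, 13L))
})

test_that("the screen cohort composition matches its design", {
  cfg <- makeScreenCohort(seed = 6)
  expect_length(cfg$wellConfigs, 67)
  sim_classes <- vapply(names(cfg$wellConfigs), function(w) {
    wc <- cfg$wellConfigs[[w]]
    if (!is.null(wc$true_class)) wc$true_class else
      classifyGenotype(vapply(wc$alleles, function(a) a$kind == "wildtype",
                              logical(1)))
  }, "")
  counts <- table(sim_classes)
  expect_equal(unname(counts["HOMOZYGOUS"]), 10L, ignore_attr = TRUE)
  expect_equal(unname(counts["COMPOUND_HETEROZYGOUS"]), 27L, ignore_attr = TRUE)
  expect_equal(unname(counts["HETEROZYGOUS"]), 4L, ignore_attr = TRUE)
  expect_equal(unname(counts["WILDTYPE"]), 2L, ignore_attr = TRUE)
  expect_equal(unname(counts["MIXED"]), 21L, ignore_attr = TRUE)
  expect_equal(unname(counts["NO_CALL"]), 3L, ignore_attr = TRUE)
  ## truth-level biallelic disruption
  s <- summarizeCohort(sim_classes)
  expect_equal(s$biallelic_disrupted, 37L)
})

test_that("FASTQ and truth files are written when paths are given", {
  lay <- exampleLayout(1, 1)
  cfg <- simConfig(lay, list(A1 = list(alleles = list(alleleWildtype()),
                                       fractions = 1, depth = 10L)))
  fq <- file.path(tempdir(), "sim.fastq")
  tr <- file.path(tempdir(), "sim_truth.tsv")
  sim <- simulateRun(cfg, seed = 3, fastqPath = fq, truthPath = tr)
  back <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_equal(length(back), 10L)
  expect_equal(unname(as.character(back)), unname(sim$reads[names(back)]))
  ttab <- read.delim(tr)
  expect_equal(nrow(ttab), 10L)
})
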