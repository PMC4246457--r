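layout <- exampleLayout()

test_that("barcode prefix matching follows minimal-distance and ambiguity rules", {
  bcs <- columnBarcodes(layout)
  ## identity
  hit <- matchBarcode(paste0(bcs[[3]], "ACGT"), bcs, maxMismatch = 0)
  expect_equal(hit$id, names(bcs)[3])
  expect_equal(hit$mismatches, 0L)
  ## one mismatch, unique
  mm1 <- mutateAt(bcs[[5]], 4)
  hit <- matchBarcode(paste0(mm1, "ACGT"), bcs, maxMismatch = 1)
  expect_equal(hit$id, names(bcs)[5])
  expect_equal(hit$mismatches, 1L)
  ## over budget
  mm2 <- mutateAt(bcs[[5]], c(2, 7))
  hit <- matchBarcode(paste0(mm2, "ACGT"), bcs, maxMismatch = 1)
  expect_true(is.na(hit$id))
  ## tie between two equidistant candidates -> no assignment
  two <- c(x = "AAAAAAAAAA", y = "AAAAAAAAAT")
  tie <- matchBarcode("AAAAAAAAAG", two, maxMismatch = 1)
  expect_true(is.na(tie$id))
  ## prefix shorter than every candidate
  short <- matchBarcode("ACGT", bcs, maxMismatch = 1)
  expect_true(is.na(short$id))
})

test_that("constructed reads assign to their well in both orientations", {
  read <- makeCleanRead(layout, 6, 1)  # column 6, row A -> A6
  a <- assignRead(read, layout)
  expect_equal(a$well, "A6")
  expect_equal(a$orientation, "plus")
  expect_equal(a$fwd_mm, 0L)
  expect_equal(a$rev_mm, 0L)
  ## trimmed sequence is the amplicon interior between the primers
  amp <- referenceAmplicon(layout)
  expect_equal(a$trimmed, substr(amp, 21, 180))

  b <- assignRead(revComp(read), layout)
  expect_equal(b$well, "A6")
  expect_equal(b$orientation, "minus")
  expect_equal(b$trimmed, a$trimmed)
})

test_that("reads with excess barcode mismatches stay unassigned", {
  read <- makeCleanRead(layout, 2, 3)
  broken <- mutateAt(read, c(1, 5))  # two errors in the column barcode
  a <- assignRead(broken, layout, DemuxParams(maxMismatch = 1))
  expect_equal(a$well, "unassigned")
  ok <- assignRead(broken, layout, DemuxParams(maxMismatch = 2))
  expect_equal(ok$well, "C2")
})

test_that("short reads and single-barcode reads get distinct unassigned reasons", {
  short <- assignRead("ACGTACGTAC", layout)
  expect_equal(short$reason, "too_short")
  ## column barcode intact, row barcode destroyed
  read <- makeCleanRead(layout, 1, 1)
  a <- assignRead(paste0(substr(read, 1, nchar(read) - 10), strrep("A", 10)),
                  layout)
  expect_equal(a$well, "unassigned")
  expect_equal(a$reason, "partial")
})

test_that("demultiplexing conserves reads and respects orientation symmetry", {
  set.seed(7)
  cols <- sample(12, 40, replace = TRUE)
  rows <- sample(8, 40, replace = TRUE)
  reads <- vapply(1:40, function(i) makeCleanRead(layout, cols[i], rows[i]), "")
  ## corrupt some reads so several bins exist
  reads[1:5] <- vapply(reads[1:5], function(r) mutateAt(r, c(1, 2, 3)), "")
  names(reads) <- paste0("r", 1:40)
  dm <- demultiplex(reads, layout)
  expect_equal(sum(dm$counts$reads) + sum(dm$assignments$well == "unassigned"),
               40L)
  ## reverse-complementing every read flips orientation, keeps wells
  dm2 <- demultiplex(setNames(revComp(reads), names(reads)), layout)
  expect_equal(dm2$assignments$well, dm$assignments$well)
  assigned <- dm$assignments$well != "unassigned"
  expect_equal(dm2$assignments$orientation[assigned],
               ifelse(dm$assignments$orientation[assigned] == "plus",
                      "minus", "plus"))
})

test_that("error-free plate round-trip bins every read correctly", {
  lay <- exampleLayout(4, 3)
  wells <- enumerateWells(lay)
  cfgs <- setNames(lapply(wells$well, function(w)
    list(alleles = list(alleleWildtype()), fractions = 1, depth = 10L)),
    wells$well)
  cfg <- simConfig(lay, cfgs, substitutionRate = 0, homopolymerIndelRate = 0,
                   barcodeErrorRate = 0)
  sim <- simulateRun(cfg, seed = 5)
  dm <- demultiplex(sim$reads, lay)
  got <- setNames(dm$assignments$well, dm$assignments$read_id)
  expect_equal(unname(got[sim$truth$read_id]), sim$truth$well)
  ## orientations also recovered exactly
  ori <- setNames(dm$assignments$orientation, dm$assignments$read_id)
  expect_equal(unname(ori[sim$truth$read_id]), sim$truth$orientation)
})

test_that("error-free reads cannot be misassigned when mismatch budget fits the code distance", {
  ## exhaustive: every barcode mutated at every position, budget 1 < (5-1)/2
  lay <- exampleLayout(3, 2)
  for (ci in 1:3) for (ri in 1:2) {
    clean <- makeCleanRead(lay, ci, ri)
    truth <- enumerateWells(lay)
    wellName <- truth$well[truth$column_label == ci &
                             truth$row_label == LETTERS[ri]]
    for (p in 1:10) {
      a <- assignRead(mutateAt(clean, p), lay, DemuxParams(maxMismatch = 1))
      expect_true(a$well %in% c(wellName, "unassigned"))
    }
  }
})

test_that("empty input produces empty bins and zero counts", {
  dm <- demultiplex(character(0), layout)
  expect_equal(nrow(dm$assignments), 0L)
  expect_equal(sum(dm$counts$reads), 0L)
})

test_that("per-well FASTQ output round-trips through a standard FASTQ reader", {
  lay <- exampleLayout(2, 2)
  reads <- c(r1 = makeCleanRead(lay, 1, 1), r2 = makeCleanRead(lay, 2, 2),
             r3 = makeCleanRead(lay, 1, 1), r4 = strrep("A", 100))
  dm <- demultiplex(reads, lay)
  out <- file.path(tempdir(), "demux_out")
  summ <- writeDemuxFastq(dm, reads, out, run = "t")
  a1 <- Biostrings::readDNAStringSet(file.path(out, "t_A1.fastq"),
                                     format = "fastq")
  expect_equal(length(a1), 2L)
  expect_equal(sort(names(a1)), c("r1", "r3"))
  una <- Biostrings::readDNAStringSet(file.path(out, "t_unassigned.fastq"),
                                      format = "fastq")
  expect_equal(as.character(una[[1]]), strrep("A", 100))
  expect_true(file.exists(file.path(out, "t_demux_summary.tsv")))
  expect_equal(sum(summ$reads), 4L)
})
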