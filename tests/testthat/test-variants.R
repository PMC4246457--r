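layout <- exampleLayout()
ref <- referenceAmplicon(layout)
cut <- cutSite(layout)

## build an alignments data.frame straight from trimmed sequences
alnFor <- function(seqs, orientation = NULL, ids = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
  a <- alignReads(setNames(seqs, ids), ref)
  a$orientation <- orientation %||% rep("plus", length(seqs))
  a
}
`%||%` <- function(a, b) if (is.null(a)) b else a
core <- substr(ref, 21, 180)
coreCut <- cut - 20  # cut position in core coordinates (0-based -> 1-based mix)

## core with a deletion of len at a 0-based amplicon position
coreDel <- function(pos, len) {
  paste0(substr(ref, 21, pos), substr(ref, pos + len + 1, 180))
}

test_that("per-read signatures capture in-window variants and park distal ones", {
  ## perfect read -> wildtype
  ex <- extractAlleles(alnFor(core), layout)
  expect_equal(ex$reads$signature, "WT")
  ## 1 nt deletion at the cut site
  ex <- extractAlleles(alnFor(coreDel(cut, 1)), layout)
  expect_match(ex$reads$signature, "^D:")
  v <- ex$variants[ex$variants$key == ex$reads$signature, ]
  expect_equal(v$kind, "deletion")
  expect_equal(v$length, 1L)
  expect_true(v$in_window)
  ## substitution 40 nt upstream of the cut: wildtype + distal candidate
  subRead <- mutateAt(core, cut - 40 - 20)     # amplicon pos cut-40
  ex <- extractAlleles(alnFor(subRead), layout, window = 25)
  expect_equal(ex$reads$signature, "WT")
  expect_equal(nrow(ex$variants), 1L)
  expect_false(ex$variants$in_window)
  expect_equal(ex$variants$kind, "substitution")
})

test_that("the strand-bias test matches closed-form binomial tails and the extremity guard", {
  bal <- strandBiasTest(50, 50, 0.5)
  expect_equal(bal$p_value, 1.0)
  expect_false(bal$biased)

  oneSided <- strandBiasTest(40, 0, 0.5)
  expect_equal(oneSided$p_value, 2 * 0.5^40, tolerance = 1e-12)
  expect_true(oneSided$biased)

  ## tiny counts can never trip the extremity guard
  small <- strandBiasTest(3, 2, 0.5)
  expect_false(small$biased)
  expect_error(strandBiasTest(0, 0, 0.5), "at least one")
})

test_that("recurrent distal artifacts are blacklisted, true alleles are not", {
  mkRows <- function(wells, position, kind, in_window, biased)
    data.frame(well = wells, position = position, kind = kind,
               in_window = in_window, biased = biased, stringsAsFactors = FALSE)
  ## artifact at position 30 in 10 of 20 wells
  art <- mkRows(paste0("W", 1:10), 30L, "substitution", FALSE, TRUE)
  allele <- mkRows(paste0("W", 1:2), 100L, "deletion", TRUE, FALSE)
  bl <- recurrenceFilter(rbind(art, allele), minWells = 3)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$position, 30L)
  expect_equal(bl$n_wells, 10L)
  ## below min_wells
  bl2 <- recurrenceFilter(art[1:2, ], minWells = 3)
  expect_equal(nrow(bl2), 0L)
  ## nothing shared
  expect_equal(nrow(recurrenceFilter(allele, minWells = 3)), 0L)
})

test_that("allele collapsing, fractions and the coverage gate behave as specified", {
  ## all-wildtype well
  cw <- callWellAlleles(alnFor(rep(core, 120),
                               orientation = rep(c("plus", "minus"), 60)),
                        layout)
  expect_equal(cw$status, "OK")
  expect_equal(nrow(cw$alleles), 1L)
  expect_equal(cw$alleles$fraction, 1.0)
  expect_true(cw$alleles$is_wildtype)

  ## compound-het composition: 60 del1 + 60 del13, balanced strands
  seqs <- c(rep(coreDel(cut, 1), 60), rep(coreDel(cut - 6, 13), 60))
  cw <- callWellAlleles(alnFor(seqs, rep(c("plus", "minus"), 60)), layout)
  expect_equal(nrow(cw$alleles), 2L)
  expect_equal(sort(cw$alleles$fraction), c(0.5, 0.5))
  expect_false(any(cw$alleles$is_wildtype))

  ## 100 wildtype + 4 plus-only substitution reads: substitution flagged
  subRead <- mutateAt(core, coreCut)
  seqs <- c(rep(core, 100), rep(subRead, 4))
  oris <- c(rep(c("plus", "minus"), 50), rep("plus", 4))
  cw <- callWellAlleles(alnFor(seqs, oris), layout)
  expect_equal(nrow(cw$alleles), 1L)
  expect_true(cw$alleles$is_wildtype)
  expect_true(any(cw$artifacts$reason %in% c("strand_bias", "low_support")))

  ## coverage below the gate
  cw <- callWellAlleles(alnFor(rep(core, 50)), layout, minCoverage = 100)
  expect_equal(cw$status, "NO_CALL")
  expect_equal(nrow(cw$alleles), 0L)
})

test_that("collapsing conserves reads across called, minor, dropped and unmapped", {
  set.seed(21)
  seqs <- c(rep(coreDel(cut, 2), 150), rep(core, 60),
            rep(coreDel(cut - 3, 7), 20),     # minor band (~8.7%)
            vapply(1:5, function(i) randomDNA(160), ""))  # unalignable
  oris <- rep(c("plus", "minus"), length.out = length(seqs))
  aln <- alnFor(seqs, oris)
  cw <- callWellAlleles(aln, layout)
  accounted <- sum(cw$alleles$read_count) + cw$stats$dropped_minor +
    cw$stats$unmapped
  expect_equal(accounted, length(seqs))
  expect_true(cw$minor_allele_evidence)
})

test_that("substitution-only alleles need the stricter fraction and balance", {
  subRead <- mutateAt(core, coreCut + 3)
  ## 22% substitution allele, balanced: above minAlleleFraction but below the
  ## substitution-only bar -> folded into wildtype
  seqs <- c(rep(core, 78), rep(subRead, 22))
  oris <- rep(c("plus", "minus"), 50)
  cw <- callWellAlleles(alnFor(seqs, oris), layout)
  expect_equal(nrow(cw$alleles), 1L)
  expect_true(cw$alleles$is_wildtype)
  expect_equal(cw$alleles$read_count, 100L)

  ## 40% substitution allele, balanced -> a real substitution allele
  seqs <- c(rep(core, 60), rep(subRead, 40))
  cw <- callWellAlleles(alnFor(seqs, oris), layout)
  expect_equal(nrow(cw$alleles), 2L)
  expect_true(any(cw$alleles$substitution_only))
})

test_that("the same physical homopolymer deletion collapses to one signature", {
  run <- regexpr("TTTTT", ref)[1]  # inside the cut window
  seqs <- unlist(lapply(0:4, function(k)
    rep(paste0(substr(ref, 21, run + k - 1), substr(ref, run + k + 1, 180)), 30)))
  cw <- callWellAlleles(alnFor(seqs, rep(c("plus", "minus"), 75)), layout,
                        minCoverage = 100)
  expect_equal(nrow(cw$alleles), 1L)
  expect_equal(cw$alleles$read_count, 150L)
  expect_match(cw$alleles$signature, "^D:")
})

test_that("signature formatting is cut-relative and 1-based", {
  expect_equal(formatSignature("WT", cut), "WT")
  expect_equal(formatSignature(sprintf("D:%d:13", cut - 2), cut), "del13@-2")
  expect_equal(formatSignature(sprintf("I:%d:2:TG", cut), cut), "ins2TG@+1")
  expect_equal(formatSignature(sprintf("S:%d:G", cut + 2), cut), "subG@+3")
})
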