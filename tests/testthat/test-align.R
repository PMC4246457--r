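layout <- exampleLayout()
ref <- referenceAmplicon(layout)

test_that("a perfect reference slice aligns end to end with full score", {
  read <- substr(ref, 21, 170)  # 150 nt interior slice
  a <- alignRead(read, ref)
  expect_equal(a$cigar, "150M")
  expect_equal(a$ref_start, 20L)
  expect_equal(a$score, 150L * 2L)
  expect_true(a$aligned)
})

test_that("an internal 13 nt deletion survives as a single D block", {
  core <- substr(ref, 21, 180)
  cut <- cutSite(layout) - 20  # cut position within the trimmed core
  delRead <- paste0(substr(core, 1, cut - 6), substr(core, cut + 8, nchar(core)))
  a <- alignRead(delRead, ref)
  blocks <- regmatches(a$cigar, gregexpr("[0-9]+[MID]", a$cigar))[[1]]
  dblocks <- grep("D$", blocks, value = TRUE)
  expect_length(dblocks, 1)
  expect_equal(dblocks, "13D")
  expect_equal(sum(as.integer(sub("[MID]", "", grep("[MI]$", blocks, value = TRUE)))),
               nchar(delRead))
})

test_that("alignment scores match the independent brute-force affine-gap oracle", {
  set.seed(101)
  n_cases <- 500
  reads <- character(n_cases); refs <- character(n_cases)
  for (i in seq_len(n_cases)) {
    refs[i] <- randomDNA(sample(100:250, 1))
    type <- i %% 3
    if (type == 0) {
      reads[i] <- randomDNA(sample(20:80, 1))      # unrelated read
    } else {
      st <- sample(1:(nchar(refs[i]) - 85), 1); len <- sample(30:80, 1)
      rd <- substr(refs[i], st, min(st + len, nchar(refs[i])))
      if (type == 1) rd <- mutateAt(rd, sample(nchar(rd), 3))  # substitutions
      else {
        dl <- sample(1:15, 1); dp <- sample(5:(nchar(rd) - 20), 1)
        rd <- paste0(substr(rd, 1, dp), substr(rd, dp + dl + 1, nchar(rd)))
      }
      reads[i] <- rd
    }
  }
  for (i in seq_len(n_cases)) {
    a <- alignReads(reads[i], refs[i])
    expect_identical(a$score, as.integer(oracleScore(reads[i], refs[i])),
                     label = paste("case", i))
  }
})

test_that("deletions of 1-50 nt away from the amplicon ends are recovered exactly", {
  set.seed(33)
  for (rep in 1:40) {
    dl <- sample(1:50, 1)
    start <- sample(30:(170 - dl), 1)          # >= 10 nt from either end
    read <- paste0(substr(ref, 15, start - 1), substr(ref, start + dl, 190))
    a <- alignRead(read, ref)
    blocks <- regmatches(a$cigar, gregexpr("[0-9]+[MID]", a$cigar))[[1]]
    dblocks <- grep("D$", blocks, value = TRUE)
    expect_length(dblocks, 1)
    expect_equal(as.integer(sub("D", "", dblocks)), dl)
  }
})

test_that("CIGAR conservation invariants hold for noisy reads", {
  set.seed(55)
  for (rep in 1:50) {
    read <- substr(ref, sample(1:30, 1), sample(150:200, 1))
    read <- mutateAt(read, sample(nchar(read), sample(0:4, 1)))
    a <- alignRead(read, ref)
    spans <- ampliclone:::.cigarSpans(a$cigar)
    expect_equal(unname(spans["read"]), nchar(read))
    expect_equal(a$ref_start + unname(spans["ref"]) <= nchar(ref), TRUE)
    ## no two adjacent CIGAR operations share an op
    ops <- regmatches(a$cigar, gregexpr("[MID]", a$cigar))[[1]]
    expect_false(any(ops[-1] == ops[-length(ops)]))
  }
})

test_that("indels are left-aligned within homopolymers and repeats", {
  ## the amplicon has a homopolymer run; deleting any one base of it must
  ## produce the same left-aligned CIGAR
  run <- regexpr("TTTTT", ref)[1]  # 1-based start of a T run
  cigars <- vapply(0:4, function(k) {
    read <- paste0(substr(ref, 21, run + k - 1), substr(ref, run + k + 1, 180))
    alignRead(read, ref)$cigar
  }, "")
  expect_length(unique(cigars), 1)
  ## and the R-side normalizer agrees with the aligner's placement
  read <- paste0(substr(ref, 21, run + 2), substr(ref, run + 4, 180))
  a <- alignRead(read, ref)
  la <- leftAlignCigar(read, ref, a$ref_start, a$cigar)
  expect_equal(la$cigar, a$cigar)
  expect_equal(la$ref_start, a$ref_start)
})

test_that("unrelated sequences fall below the alignment floor", {
  set.seed(9)
  junk <- randomDNA(150)
  a <- alignRead(junk, ref)
  expect_false(a$aligned)
})

test_that("insertions are reported as I blocks at the insertion point", {
  core <- substr(ref, 21, 180)
  ins <- "TTAGGCAT"
  read <- paste0(substr(core, 1, 80), ins, substr(core, 81, 160))
  a <- alignRead(read, ref)
  expect_match(a$cigar, "^[0-9]+M8I[0-9]+M$")
  spans <- ampliclone:::.cigarSpans(a$cigar)
  expect_equal(unname(spans["read"]), nchar(read))
})

test_that("SAM output follows conventions and round-trips through Rsamtools", {
  tmp <- file.path(tempdir(), "test.sam")
  ## header-only
  empty <- alignReads(character(0), ref)
  writeSam(empty, layout, tmp)
  lines <- readLines(tmp)
  expect_true(all(startsWith(lines, "@")))

  aln <- data.frame(read = substr(ref, 11, 160), score = 300L, ref_start = 10L,
                    cigar = "150M", aligned = TRUE, read_id = "r1",
                    orientation = "plus", stringsAsFactors = FALSE)
  aln2 <- aln; aln2$read_id <- "r2"; aln2$orientation <- "minus"
  writeSam(rbind(aln, aln2), layout, tmp)
  body <- grep("^@", readLines(tmp), invert = TRUE, value = TRUE)
  f1 <- strsplit(body[1], "\t")[[1]]
  expect_equal(f1[4], "11")      # POS is 1-based
  expect_equal(f1[2], "0")
  f2 <- strsplit(body[2], "\t")[[1]]
  expect_equal(f2[2], "16")      # minus orientation -> reverse FLAG
  expect_equal(f2[10], f1[10])   # SEQ stored in reference orientation

  bam <- Rsamtools::asBam(tmp, file.path(tempdir(), "test"),
                          overwrite = TRUE, indexDestination = FALSE)
  parsed <- Rsamtools::scanBam(bam)[[1]]
  expect_equal(as.integer(parsed$pos), c(11L, 11L))
  expect_equal(as.character(parsed$cigar), c("150M", "150M"))
})
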