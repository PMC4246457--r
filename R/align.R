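#' Construct a ScoringScheme
#'
#' Defaults (match +2, mismatch 4, gap open 5, gap extend 1) deliberately make
#' gap extension cheap relative to opening, so that a 10-50 nt CRISPR deletion
#' is kept as a single gap (cost 5 + L) rather than being shredded into
#' mismatches and short gaps.
#'
#' @param match,mismatch,gapOpen,gapExtend integer scores/penalties; a gap of
#'   length L costs \code{gapOpen + L * gapExtend}.
#' @param minScoreFrac unalignable floor: alignments scoring below
#'   \code{minScoreFrac * match * nchar(read)} are reported unaligned.
#' @return a \linkS4class{ScoringScheme}.
#' @export
ScoringScheme <- function(match = 2L, mismatch = 4L, gapOpen = 5L,
                          gapExtend = 1L, minScoreFrac = 0.4) {
  new("ScoringScheme", match = as.integer(match), mismatch = as.integer(mismatch),
      gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
      minScoreFrac = as.numeric(minScoreFrac))
}

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme (glocal): match +", object@match, ", mismatch -",
      object@mismatch, ", gap ", object@gapOpen, "+", object@gapExtend,
      "*L, floor ", object@minScoreFrac, " * match * readlen\n", sep = "")
})

## ---- CIGAR helpers ------------------------------------------------------

.parseCigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar, call. = FALSE)
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

.cigarString <- function(blocks) {
  if (nrow(blocks) == 0) return("")
  paste0(blocks$len, blocks$op, collapse = "")
}

## merge adjacent blocks with the same op, drop zero-length blocks
.mergeBlocks <- function(blocks) {
  blocks <- blocks[blocks$len > 0L, , drop = FALSE]
  if (nrow(blocks) < 2) return(blocks)
  keep <- c(TRUE, blocks$op[-1] != blocks$op[-nrow(blocks)])
  grp <- cumsum(keep)
  data.frame(len = as.integer(tapply(blocks$len, grp, sum)),
             op = blocks$op[keep], stringsAsFactors = FALSE)
}

#' Left-align indels in a glocal alignment
#'
#' Shifts every insertion and deletion maximally left within repeats and
#' homopolymers without changing the alignment score, so that reads carrying
#' the same physical indel always produce the same CIGAR (the standard indel
#' normalization convention).
#'
#' @param read,ref aligned read (trimmed) and reference sequences.
#' @param ref_start 0-based reference offset of the alignment.
#' @param cigar CIGAR string with ops M, I, D.
#' @return list with possibly updated \code{ref_start} and \code{cigar}.
#' @export
leftAlignCigar <- function(read, ref, ref_start, cigar) {
  blocks <- .parseCigar(cigar)
  refc <- strsplit(ref, "")[[1]]
  readc <- strsplit(read, "")[[1]]
  repeat {
    blocks <- .mergeBlocks(blocks)
    changed <- FALSE
    ## positions of each block start: ref offset and read offset
    k <- 1L
    rpos <- ref_start          # 0-based ref offset of current block
    qpos <- 0L                 # 0-based read offset
    while (k <= nrow(blocks)) {
      op <- blocks$op[k]; L <- blocks$len[k]
      if (op %in% c("I", "D") && k > 1L && blocks$op[k - 1L] == "M") {
        prevM <- blocks$len[k - 1L]
        s <- 0L
        if (op == "D") {
          ## shift valid while ref base entering on the right equals the one
          ## leaving on the left (1-based chars: rpos - t + 1 vs rpos + L - t)
          while (s < prevM && rpos - s - 1L >= 0L &&
                 refc[rpos - s] == refc[rpos + L - s]) s <- s + 1L
        } else {
          while (s < prevM && qpos - s - 1L >= 0L &&
                 readc[qpos - s] == readc[qpos + L - s]) s <- s + 1L
        }
        if (s > 0L) {
          blocks$len[k - 1L] <- blocks$len[k - 1L] - s
          if (k < nrow(blocks) && blocks$op[k + 1L] == "M") {
            blocks$len[k + 1L] <- blocks$len[k + 1L] + s
          } else {
            blocks <- rbind(blocks[seq_len(k), , drop = FALSE],
                            data.frame(len = s, op = "M", stringsAsFactors = FALSE),
                            if (k < nrow(blocks)) blocks[(k + 1L):nrow(blocks), , drop = FALSE])
          }
          changed <- TRUE
          break  # re-scan from the top after any shift
        }
      }
      if (op %in% c("M", "D")) rpos <- rpos + L
      if (op %in% c("M", "I")) qpos <- qpos + L
      k <- k + 1L
    }
    if (!changed) break
  }
  blocks <- .mergeBlocks(blocks)
  ## a deletion shifted to the alignment start is a free reference overhang
  if (nrow(blocks) && blocks$op[1] == "D") {
    ref_start <- ref_start + blocks$len[1]
    blocks <- blocks[-1, , drop = FALSE]
  }
  list(ref_start = ref_start, cigar = .cigarString(blocks))
}

## ---- alignment ----------------------------------------------------------

#' Align trimmed reads to the reference amplicon
#'
#' Glocal affine-gap alignment: the whole read must align (after barcode and
#' primer trimming the read is amplicon-derived end to end) while reference
#' overhangs are free. Identical input sequences are aligned once and the
#' result reused. Indels are left-aligned so allele signatures are canonical.
#'
#' @param reads character vector of trimmed read sequences (names kept).
#' @param reference reference amplicon sequence.
#' @param scoring a \linkS4class{ScoringScheme}.
#' @return data.frame with one row per read: \code{read} (sequence),
#'   \code{score}, \code{ref_start} (0-based), \code{cigar}, \code{aligned}
#'   (FALSE when the score falls below the unalignable floor).
#' @export
alignReads <- function(reads, reference, scoring = ScoringScheme()) {
  validObject(scoring)
  .assertDNA(reference, "reference")
  if (length(reads) == 0) {
    return(data.frame(read = character(0), score = integer(0),
                      ref_start = integer(0), cigar = character(0),
                      aligned = logical(0), stringsAsFactors = FALSE))
  }
  if (!all(grepl("^[ACGT]+$", reads))) stop("reads must be A/C/G/T strings", call. = FALSE)
  uniq <- unique(reads)
  ## indels come back already left-aligned (same convention as leftAlignCigar)
  raw <- cpp_align_glocal(uniq, reference, scoring@match, scoring@mismatch,
                          scoring@gapOpen, scoring@gapExtend)
  floor_ <- scoring@minScoreFrac * scoring@match * nchar(uniq)
  raw$aligned <- raw$score >= floor_
  i <- match(reads, uniq)
  out <- data.frame(read = unname(reads), score = raw$score[i],
                    ref_start = raw$ref_start[i], cigar = raw$cigar[i],
                    aligned = raw$aligned[i], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(names(reads))) out$read_id <- names(reads)
  out
}

#' Align a single trimmed read
#'
#' @inheritParams alignReads
#' @param read a single trimmed read sequence.
#' @return one-row data.frame as in \code{\link{alignReads}}.
#' @export
alignRead <- function(read, reference, scoring = ScoringScheme()) {
  alignReads(read, reference, scoring)
}

## CIGAR length sums: read span (M+I) and reference span (M+D)
.cigarSpans <- function(cigar) {
  b <- .parseCigar(cigar)
  c(read = sum(b$len[b$op %in% c("M", "I")]),
    ref = sum(b$len[b$op %in% c("M", "D")]))
}

## ---- SAM output ---------------------------------------------------------

#' Write alignments to a SAM file
#'
#' Emits a valid single-reference SAM (the amplicon) that loads in IGV and
#' round-trips through standard parsers. Reads demultiplexed from the minus
#' orientation carry the reverse-strand FLAG; SEQ is always stored in
#' reference (plus) orientation, as the SAM convention requires.
#'
#' @param alignments data.frame from \code{\link{alignReads}}; an
#'   \code{orientation} column ("plus"/"minus") and \code{read_id} column are
#'   honoured when present. Rows with \code{aligned == FALSE} are skipped.
#' @param layout a \linkS4class{PlateLayout} (provides the reference name and
#'   length for the header).
#' @param path output SAM path.
#' @param refName reference sequence name in the header (default "amplicon").
#' @return \code{path}, invisibly.
#' @export
writeSam <- function(alignments, layout, path, refName = "amplicon") {
  reflen <- nchar(referenceAmplicon(layout))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", refName, "\tLN:", reflen),
               "@PG\tID:ampliclone\tPN:ampliclone"), con)
  if (nrow(alignments) == 0) return(invisible(path))
  keep <- if ("aligned" %in% names(alignments)) alignments$aligned else TRUE
  aln <- alignments[keep, , drop = FALSE]
  if (nrow(aln) == 0) return(invisible(path))
  ids <- if ("read_id" %in% names(aln)) aln$read_id else paste0("read", seq_len(nrow(aln)))
  ori <- if ("orientation" %in% names(aln)) aln$orientation else "plus"
  flag <- ifelse(ori == "minus", 16L, 0L)
  qual <- if ("qualities" %in% names(aln)) aln$qualities else
    vapply(nchar(aln$read), function(n) strrep(.SIM_QUAL, n), character(1))
  lines <- paste(ids, flag, refName, aln$ref_start + 1L, 60L, aln$cigar,
                 "*", 0L, 0L, aln$read, qual, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write the reference amplicon as FASTA
#' @param layout a \linkS4class{PlateLayout}.
#' @param path output FASTA path.
#' @param refName sequence name (default "amplicon").
#' @return \code{path}, invisibly.
#' @export
writeReferenceFasta <- function(layout, path, refName = "amplicon") {
  seqs <- Biostrings::DNAStringSet(referenceAmplicon(layout))
  names(seqs) <- refName
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
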