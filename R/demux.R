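#' Construct DemuxParams
#'
#' @param maxMismatch maximum substitutions tolerated per barcode (default 1;
#'   with barcode sets of minimum pairwise distance d, any value up to
#'   floor((d-1)/2) keeps error-free assignment unambiguous).
#' @param requireBothBarcodes logical; the well identity is the barcode
#'   \emph{pair}, so a read in which only one barcode is recognized can never
#'   be assigned to a well. Kept configurable for reporting purposes: such
#'   reads are tallied under the unassigned reason "partial".
#' @param minReadLength reads shorter than this are rejected as "too_short".
#'   Default: both barcodes plus both primers plus 20 nt of insert.
#' @param endSlop 3'-end anchoring slop for the trailing barcode (default 2),
#'   tolerating a little adaptor-trimming jitter at the read end.
#' @return a \linkS4class{DemuxParams}.
#' @export
DemuxParams <- function(maxMismatch = 1L, requireBothBarcodes = TRUE,
                        minReadLength = 60L, endSlop = 2L) {
  new("DemuxParams", maxMismatch = as.integer(maxMismatch),
      requireBothBarcodes = isTRUE(requireBothBarcodes),
      minReadLength = as.integer(minReadLength), endSlop = as.integer(endSlop))
}

setMethod("show", "DemuxParams", function(object) {
  cat("DemuxParams: maxMismatch", object@maxMismatch,
      "| minReadLength", object@minReadLength,
      "| endSlop", object@endSlop,
      "| requireBothBarcodes", object@requireBothBarcodes, "\n")
})

#' Match a read prefix against a barcode set
#'
#' Returns the unique candidate at minimal Hamming distance to the
#' equal-length prefix, provided that distance is at most \code{maxMismatch}.
#' A tie between two distinct candidates at the minimal distance returns no
#' match: an ambiguous read must never be assigned arbitrarily. Candidates
#' longer than the prefix are skipped.
#'
#' @param prefix leading read sequence (at least as long as the barcodes).
#' @param candidates named character vector of barcode sequences.
#' @param maxMismatch maximum tolerated mismatches.
#' @return list with \code{id} (NA when unmatched), \code{barcode},
#'   \code{mismatches}.
#' @export
matchBarcode <- function(prefix, candidates, maxMismatch = 1L) {
  if (length(candidates) == 0) stop("no candidate barcodes", call. = FALSE)
  if (is.null(names(candidates))) names(candidates) <- paste0("bc", seq_along(candidates))
  d <- vapply(candidates, function(b) {
    L <- nchar(b)
    if (nchar(prefix) < L) return(NA_integer_)
    sum(strsplit(substr(prefix, 1L, L), "")[[1]] != strsplit(b, "")[[1]])
  }, integer(1))
  if (all(is.na(d))) return(list(id = NA_character_, barcode = NA_character_,
                                 mismatches = NA_integer_))
  dmin <- min(d, na.rm = TRUE)
  hits <- which(!is.na(d) & d == dmin)
  if (dmin > maxMismatch || length(hits) != 1)
    return(list(id = NA_character_, barcode = NA_character_, mismatches = NA_integer_))
  list(id = names(candidates)[hits], barcode = unname(candidates[hits]),
       mismatches = as.integer(dmin))
}

## Vectorized anchored matching of one barcode set against many reads.
## side = "start": barcode anchored at position 0.
## side = "end": the reverse complement of each barcode anchored within
## `slop` bases of the 3' terminus (minimal distance over offsets, smaller
## offset preferred at ties).
## Returns list(idx = candidate index or NA, mm, off).
.matchAnchored <- function(reads, barcodes, maxMismatch, side = "start", slop = 0L) {
  n <- length(reads)
  lens <- nchar(reads)
  k <- length(barcodes)
  dist <- matrix(NA_integer_, n, k)
  off <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    bc <- if (side == "start") barcodes[[j]] else revComp(barcodes[[j]])
    L <- nchar(bc)
    if (side == "start") {
      dist[, j] <- cpp_hamming_at(reads, bc, rep.int(0L, n))
    } else {
      best <- rep(NA_integer_, n); bestoff <- rep(0L, n)
      for (o in 0:slop) {
        d <- cpp_hamming_at(reads, bc, lens - L - o)
        upd <- !is.na(d) & (is.na(best) | d < best)
        best[upd] <- d[upd]; bestoff[upd] <- o
      }
      dist[, j] <- best; off[, j] <- bestoff
    }
  }
  dmin <- suppressWarnings(apply(dist, 1, min, na.rm = TRUE))
  dmin[!is.finite(dmin)] <- NA_integer_
  nmin <- rowSums(!is.na(dist) & dist == dmin, na.rm = FALSE)
  nmin[is.na(dmin)] <- 0L
  ok <- !is.na(dmin) & dmin <= maxMismatch & nmin == 1L
  idx <- rep(NA_integer_, n)
  idx[ok] <- max.col(-replace(dist, is.na(dist), .Machine$integer.max), "first")[ok]
  mm <- ifelse(ok, dmin, NA_integer_)
  ooff <- rep(NA_integer_, n)
  ooff[ok] <- off[cbind(which(ok), idx[ok])]
  list(idx = idx, mm = as.integer(mm), off = ooff)
}

## Attempt plus-layout assignment of reads presented in a given orientation:
## column barcode leading, reverse-complemented row barcode trailing.
.tryLayout <- function(reads, layout, params) {
  col <- .matchAnchored(reads, columnBarcodes(layout), params@maxMismatch,
                        side = "start")
  row <- .matchAnchored(reads, rowBarcodes(layout), params@maxMismatch,
                        side = "end", slop = params@endSlop)
  list(col = col, row = row, both = !is.na(col$idx) & !is.na(row$idx))
}

#' Demultiplex pooled reads into per-well bins
#'
#' Each read is assigned to a well by recognizing its column barcode at the
#' 5' start and its (reverse-complemented) row barcode at the 3' end. Both
#' orientations are tried: a read beginning with a column barcode is labelled
#' \code{plus}, one beginning with a row barcode (i.e. matching after
#' reverse-complementation) is \code{minus}. For single-end amplicon data this
#' orientation is the strand signal consumed by the strand-bias artifact
#' filter downstream. Barcodes and target primers are trimmed from assigned
#' reads.
#'
#' @param reads a named character vector of read sequences, a
#'   \code{Biostrings::DNAStringSet}, or a path to a FASTQ file (plain or
#'   gzipped, phred+33).
#' @param layout a \linkS4class{PlateLayout}.
#' @param params a \linkS4class{DemuxParams}.
#' @return a list of class \code{DemuxResult}: \code{assignments} (one row per
#'   read: read_id, well, orientation, fwd_mm, rev_mm, reason, trimmed,
#'   qualities), \code{counts} (per-well read counts over all layout wells),
#'   \code{unassigned} (reason tally), \code{params}.
#' @export
demultiplex <- function(reads, layout, params = DemuxParams()) {
  validObject(layout); validObject(params)
  inp <- .readInput(reads)
  seqs <- inp$seq; quals <- inp$qual
  n <- length(seqs)
  wells <- enumerateWells(layout)
  ## lookup [column index, row index] -> well name
  wellOf <- matrix(NA_character_, length(columnBarcodes(layout)),
                   length(rowBarcodes(layout)))
  wellOf[cbind(wells$column_label, match(wells$row_label, LETTERS))] <- wells$well

  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read%d", seq_len(n))
  out <- data.frame(read_id = ids,
                    well = rep("unassigned", n),
                    orientation = rep(NA_character_, n),
                    fwd_mm = rep(NA_integer_, n), rev_mm = rep(NA_integer_, n),
                    reason = rep(NA_character_, n),
                    trimmed = rep(NA_character_, n),
                    qualities = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0) return(.demuxResult(out, wells, params))

  tooShort <- nchar(seqs) < params@minReadLength
  out$reason[tooShort] <- "too_short"
  live <- which(!tooShort)

  partial <- logical(n)
  if (length(live)) {
    plus <- .tryLayout(seqs[live], layout, params)
    assignP <- live[plus$both]
    if (length(assignP)) {
      i <- match(assignP, live)
      out$well[assignP] <- wellOf[cbind(plus$col$idx[i], plus$row$idx[i])]
      out$orientation[assignP] <- "plus"
      out$fwd_mm[assignP] <- plus$col$mm[i]
      out$rev_mm[assignP] <- plus$row$mm[i]
      tr <- .trimReads(seqs[assignP], quals[assignP],
                       nchar(columnBarcodes(layout))[plus$col$idx[i]],
                       nchar(rowBarcodes(layout))[plus$row$idx[i]],
                       plus$row$off[i], layout)
      out$trimmed[assignP] <- tr$seq; out$qualities[assignP] <- tr$qual
    }
    rest <- live[!plus$both]
    partial[rest] <- (!is.na(plus$col$idx) | !is.na(plus$row$idx))[match(rest, live)]
    if (length(rest)) {
      rcseq <- revComp(seqs[rest])
      minus <- .tryLayout(rcseq, layout, params)
      assignM <- rest[minus$both]
      if (length(assignM)) {
        i <- match(assignM, rest)
        out$well[assignM] <- wellOf[cbind(minus$col$idx[i], minus$row$idx[i])]
        out$orientation[assignM] <- "minus"
        out$fwd_mm[assignM] <- minus$col$mm[i]
        out$rev_mm[assignM] <- minus$row$mm[i]
        rq <- quals[assignM]
        rq <- ifelse(is.na(rq), rq, vapply(rq, function(q)
          paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1), USE.NAMES = FALSE))
        tr <- .trimReads(rcseq[i], rq,
                         nchar(columnBarcodes(layout))[minus$col$idx[i]],
                         nchar(rowBarcodes(layout))[minus$row$idx[i]],
                         minus$row$off[i], layout)
        out$trimmed[assignM] <- tr$seq; out$qualities[assignM] <- tr$qual
      }
      failed <- rest[!minus$both]
      if (length(failed)) {
        i <- match(failed, rest)
        anyBC <- partial[failed] | (!is.na(minus$col$idx) | !is.na(minus$row$idx))[i]
        out$reason[failed] <- ifelse(anyBC, "partial", "no_barcode")
      }
    }
  }
  .demuxResult(out, wells, params)
}

## barcode/primer removal; endOff = trailing slop bases beyond the row barcode
.trimReads <- function(seqs, quals, colLen, rowLen, endOff, layout) {
  from <- colLen + nchar(fwdPrimer(layout)) + 1L
  to <- nchar(seqs) - endOff - rowLen - nchar(revPrimer(layout))
  bad <- to < from
  s <- substr(seqs, from, to)
  q <- ifelse(is.na(quals), NA_character_, substr(quals, from, to))
  s[bad] <- ""
  list(seq = unname(s), qual = unname(q))
}

.demuxResult <- function(assignments, wells, params) {
  counts <- data.frame(well = wells$well,
                       reads = as.integer(table(factor(assignments$well,
                                                       levels = wells$well))),
                       stringsAsFactors = FALSE)
  una <- assignments$reason[assignments$well == "unassigned"]
  una <- table(una, useNA = "no")
  structure(list(assignments = assignments, counts = counts,
                 unassigned = as.data.frame(una, stringsAsFactors = FALSE),
                 params = params),
            class = "DemuxResult")
}

#' @export
print.DemuxResult <- function(x, ...) {
  n <- nrow(x$assignments)
  assigned <- sum(x$assignments$well != "unassigned")
  cat("DemuxResult:", n, "reads,", assigned, "assigned (",
      if (n > 0) round(100 * assigned / n, 1) else 0, "% ) across",
      sum(x$counts$reads > 0), "wells\n")
  invisible(x)
}

## accept character vector / DNAStringSet / FASTQ path
.readInput <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    x <- Biostrings::readDNAStringSet(reads, format = "fastq", with.qualities = TRUE)
    q <- as.character(S4Vectors::mcols(x)$qualities)
    s <- as.character(x)
    ## keep only the record id (strip description after first whitespace)
    names(s) <- sub("\\s.*$", "", names(s))
    return(list(seq = s, qual = q))
  }
  if (methods::is(reads, "DNAStringSet")) {
    q <- S4Vectors::mcols(reads)$qualities
    return(list(seq = as.character(reads),
                qual = if (is.null(q)) rep(NA_character_, length(reads)) else as.character(q)))
  }
  if (is.character(reads)) {
    q <- attr(reads, "qualities")
    return(list(seq = reads,
                qual = if (is.null(q)) rep(NA_character_, length(reads)) else q))
  }
  stop("reads must be a character vector, DNAStringSet or FASTQ path", call. = FALSE)
}

#' Assign a single read to a well
#'
#' @param read a single read sequence.
#' @param layout a \linkS4class{PlateLayout}.
#' @param params a \linkS4class{DemuxParams}.
#' @return one-row assignment data.frame (see \code{\link{demultiplex}}).
#' @export
assignRead <- function(read, layout, params = DemuxParams()) {
  demultiplex(stats::setNames(read, "read1"), layout, params)$assignments
}

#' Write per-well FASTQ bins and a demultiplexing summary
#'
#' Writes \code{<run>_<well>.fastq} for every well that received reads, an
#' \code{<run>_unassigned.fastq} with the original (untrimmed) unassigned
#' reads, and \code{<run>_demux_summary.tsv} (well, reads, fraction).
#' Assigned reads are written trimmed (barcodes and primers removed), in plus
#' orientation.
#'
#' @param result a \code{DemuxResult} from \code{\link{demultiplex}}.
#' @param reads the same reads object given to \code{\link{demultiplex}}
#'   (needed to recover unassigned read sequences).
#' @param outDir output directory (created if missing).
#' @param run run name prefix (default "run1").
#' @return the summary data.frame, invisibly.
#' @export
writeDemuxFastq <- function(result, reads, outDir, run = "run1") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inp <- .readInput(reads)
  a <- result$assignments
  .writeFq <- function(seqs, quals, ids, path) {
    if (length(seqs) == 0) { file.create(path); return(invisible()) }
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    quals[is.na(quals)] <- vapply(nchar(seqs)[is.na(quals)], strrep,
                                  character(1), x = .SIM_QUAL)
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  for (w in unique(a$well[a$well != "unassigned"])) {
    i <- which(a$well == w)
    .writeFq(a$trimmed[i], a$qualities[i], a$read_id[i],
             file.path(outDir, paste0(run, "_", w, ".fastq")))
  }
  i <- which(a$well == "unassigned")
  .writeFq(inp$seq[i], inp$qual[i], a$read_id[i],
           file.path(outDir, paste0(run, "_unassigned.fastq")))
  total <- nrow(a)
  summ <- rbind(
    data.frame(well = result$counts$well, reads = result$counts$reads,
               stringsAsFactors = FALSE),
    data.frame(well = "unassigned", reads = sum(a$well == "unassigned"),
               stringsAsFactors = FALSE))
  summ$fraction <- if (total > 0) summ$reads / total else 0
  write.table(summ, file.path(outDir, paste0(run, "_demux_summary.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summ)
}
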