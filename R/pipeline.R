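#' Run the full screening workflow
#'
#' Executes demultiplex -> align -> allele calling -> genotype -> QC on one
#' pooled run. Allele calling is two-pass: a first pass over all wells
#' collects strand-biased out-of-window variants, the cross-well recurrence
#' blacklist is built from them, and a second pass applies it.
#'
#' @param reads pooled reads: named character vector, DNAStringSet or FASTQ
#'   path (see \code{\link{demultiplex}}).
#' @param layout a \linkS4class{PlateLayout}.
#' @param demuxParams a \linkS4class{DemuxParams}.
#' @param scoring a \linkS4class{ScoringScheme}.
#' @param window cut-site window half-width (default 25 nt).
#' @param minCoverage per-well coverage gate (default 100 aligned reads).
#' @param minAlleleFraction minimum called-allele fraction (default 0.20).
#' @param minWellsRecurrent recurrence blacklist threshold (default 3 wells).
#' @param outDir optional directory: persist all reports as TSV plus the run
#'   manifest; with \code{samOut} also one SAM per well and the reference
#'   FASTA.
#' @param samOut write per-well SAM files under \code{outDir/sam}
#'   (default FALSE).
#' @param run run name used in file names (default "run1").
#' @param ... further arguments to \code{\link{callWellAlleles}}.
#' @return list: \code{demux} (DemuxResult), \code{genotypes} (one row per
#'   occupied well: class, allele strings, fractions, frameshift,
#'   minor-evidence and coverage columns), \code{alleleTable} (one row per
#'   called allele), \code{summary} (\code{\link{summarizeCohort}} result),
#'   \code{qc} (\code{\link{coverageQC}} result or NULL if nothing was
#'   assigned), \code{blacklist}, \code{manifest} (every effective parameter).
#' @export
runPipeline <- function(reads, layout, demuxParams = DemuxParams(),
                        scoring = ScoringScheme(), window = 25L,
                        minCoverage = 100L, minAlleleFraction = 0.20,
                        minWellsRecurrent = 3L, outDir = NULL,
                        samOut = FALSE, run = "run1", ...) {
  validObject(layout)
  manifest <- list(
    tool = "ampliclone", version = as.character(utils::packageVersion("ampliclone")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    run = run,
    maxMismatch = demuxParams@maxMismatch,
    requireBothBarcodes = demuxParams@requireBothBarcodes,
    minReadLength = demuxParams@minReadLength,
    endSlop = demuxParams@endSlop,
    match = scoring@match, mismatch = scoring@mismatch,
    gapOpen = scoring@gapOpen, gapExtend = scoring@gapExtend,
    minScoreFrac = scoring@minScoreFrac,
    window = window, minCoverage = minCoverage,
    minAlleleFraction = minAlleleFraction,
    minWellsRecurrent = minWellsRecurrent)

  dm <- demultiplex(reads, layout, demuxParams)
  a <- dm$assignments
  assigned <- a[a$well != "unassigned", , drop = FALSE]
  if (nrow(a) > 0 && nrow(assigned) / nrow(a) < 0.01)
    warning("fewer than 1% of reads were assigned: layout/FASTQ mismatch?",
            call. = FALSE)

  occupied <- unique(assigned$well)
  occupied <- occupied[order(match(occupied, enumerateWells(layout)$well))]

  ## align per well
  wellAln <- lapply(occupied, function(w) {
    i <- which(assigned$well == w)
    keep <- nchar(assigned$trimmed[i]) > 0
    i <- i[keep]
    if (length(i) == 0) {
      return(data.frame(read = character(0), score = integer(0),
                        ref_start = integer(0), cigar = character(0),
                        aligned = logical(0), read_id = character(0),
                        orientation = character(0), stringsAsFactors = FALSE))
    }
    aln <- alignReads(stats::setNames(assigned$trimmed[i], assigned$read_id[i]),
                      referenceAmplicon(layout), scoring)
    aln$orientation <- assigned$orientation[i]
    aln
  })
  names(wellAln) <- occupied

  ## variant extraction is deterministic per well: do it once, reuse per pass
  wellExtr <- lapply(occupied, function(w)
    extractAlleles(wellAln[[w]], layout, window))
  names(wellExtr) <- occupied

  ## pass 1: artifact candidates for the recurrence blacklist
  pass1 <- lapply(occupied, function(w)
    callWellAlleles(wellAln[[w]], layout, window = window,
                    minCoverage = minCoverage,
                    minAlleleFraction = minAlleleFraction,
                    extraction = wellExtr[[w]], ...))
  names(pass1) <- occupied
  cand <- do.call(rbind, lapply(occupied, function(w) {
    ac <- pass1[[w]]$artifact_candidates
    if (is.null(ac) || nrow(ac) == 0) return(NULL)
    cbind(well = w, ac, stringsAsFactors = FALSE)
  }))
  blacklist <- recurrenceFilter(cand, minWells = minWellsRecurrent)

  ## pass 2: final calls with the blacklist applied
  calls <- lapply(occupied, function(w)
    callWellAlleles(wellAln[[w]], layout, window = window,
                    minCoverage = minCoverage,
                    minAlleleFraction = minAlleleFraction,
                    blacklist = blacklist, extraction = wellExtr[[w]], ...))
  names(calls) <- occupied

  genotypes <- do.call(rbind, lapply(occupied, function(w) {
    cw <- calls[[w]]
    cls <- if (cw$status == "NO_CALL") "NO_CALL" else
      classifyGenotype(cw$alleles, cw$minor_allele_evidence)
    alleleStr <- if (nrow(cw$alleles))
      paste(vapply(cw$alleles$signature, formatSignature, character(1),
                   cutSite = cutSite(layout)), collapse = " / ") else ""
    fs <- if (nrow(cw$alleles))
      paste(vapply(cw$alleles$signature, annotateFrameshift, character(1)),
            collapse = " / ") else ""
    data.frame(well = w, class = cls,
               coverage = cw$stats$aligned,
               n_alleles = nrow(cw$alleles),
               alleles = alleleStr,
               fractions = paste(round(cw$alleles$fraction, 3), collapse = " / "),
               frameshift = fs,
               minor_allele_evidence = cw$minor_allele_evidence,
               plus_fraction = round(cw$stats$plus_fraction, 3),
               stringsAsFactors = FALSE)
  }))

  alleleTable <- do.call(rbind, lapply(occupied, function(w) {
    al <- calls[[w]]$alleles
    if (nrow(al) == 0) return(NULL)
    data.frame(well = w, rank = seq_len(nrow(al)),
               allele = vapply(al$signature, formatSignature, character(1),
                               cutSite = cutSite(layout)),
               read_count = al$read_count, plus = al$plus_count,
               minus = al$minus_count, fraction = round(al$fraction, 4),
               stringsAsFactors = FALSE)
  }))

  summary <- summarizeCohort(genotypes)
  qc <- NULL
  depths <- stats::setNames(
    vapply(occupied, function(w) calls[[w]]$stats$aligned, 0L), occupied)
  if (length(depths) && any(depths >= 1)) qc <- coverageQC(depths)

  res <- list(demux = dm, genotypes = genotypes, alleleTable = alleleTable,
              summary = summary, qc = qc, blacklist = blacklist,
              calls = calls, manifest = manifest)
  if (!is.null(outDir)) .persistReports(res, reads, layout, wellAln, outDir,
                                        samOut, run)
  res
}

.persistReports <- function(res, reads, layout, wellAln, outDir, samOut, run) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pre <- function(f) file.path(outDir, paste0(run, "_", f))
  writeDemuxFastq(res$demux, reads, outDir, run)
  if (!is.null(res$genotypes))
    write.table(res$genotypes, pre("genotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(res$alleleTable))
    write.table(res$alleleTable, pre("alleles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  s <- res$summary
  summDf <- data.frame(
    metric = c(names(s$counts), "total", "callable", "biallelic_disrupted",
               "mutated_including_nocall", "mutated_excluding_nocall"),
    value = c(unname(s$counts), s$total, s$callable, s$biallelic_disrupted,
              s$mutated_including_nocall, s$mutated_excluding_nocall),
    stringsAsFactors = FALSE)
  write.table(summDf, pre("cohort_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$qc)) writeCoverageQC(res$qc, pre("qc.tsv"))
  manif <- res$manifest
  writeLines(paste(names(manif), vapply(manif, as.character, ""), sep = "\t"),
             pre("manifest.tsv"))
  if (samOut) {
    samDir <- file.path(outDir, "sam")
    dir.create(samDir, showWarnings = FALSE)
    writeReferenceFasta(layout, file.path(samDir, "amplicon.fasta"))
    for (w in names(wellAln))
      writeSam(wellAln[[w]], layout,
               file.path(samDir, paste0(run, "_", w, ".sam")))
  }
  invisible(res)
}
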