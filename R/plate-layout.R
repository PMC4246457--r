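#' Construct a PlateLayout
#'
#' @param columnBarcodes named character vector of column (forward) barcode
#'   sequences, in plate-column order (at most 12).
#' @param rowBarcodes named character vector of row (reverse) barcode
#'   sequences, in plate-row order (at most 8).
#' @param fwdPrimer,revPrimer target-specific primer sequences. The forward
#'   primer must be the 5' prefix of \code{referenceAmplicon}; the reverse
#'   primer must be the reverse complement of its 3' suffix.
#' @param referenceAmplicon reference amplicon sequence spanning the cut site.
#' @param cutSite cut-site position in the amplicon, \emph{1-based} as in the
#'   layout config file; stored 0-based internally.
#' @param flank design flank (nt either side of the guide); defaults to half
#'   the amplicon length.
#' @return a validated \linkS4class{PlateLayout}.
#' @export
PlateLayout <- function(columnBarcodes, rowBarcodes, fwdPrimer, revPrimer,
                        referenceAmplicon, cutSite, flank = NULL) {
  if (is.null(names(columnBarcodes)))
    names(columnBarcodes) <- paste0("col", seq_along(columnBarcodes))
  if (is.null(names(rowBarcodes)))
    names(rowBarcodes) <- paste0("row", seq_along(rowBarcodes))
  if (is.null(flank)) flank <- nchar(referenceAmplicon) %/% 2L
  obj <- new("PlateLayout",
    columnBarcodes = columnBarcodes, rowBarcodes = rowBarcodes,
    fwdPrimer = fwdPrimer, revPrimer = revPrimer,
    referenceAmplicon = referenceAmplicon,
    cutSite = as.integer(cutSite) - 1L, flank = as.integer(flank))
  if (substr(referenceAmplicon, 1L, nchar(fwdPrimer)) != fwdPrimer)
    stop("fwdPrimer is not the 5' prefix of the reference amplicon", call. = FALSE)
  n <- nchar(referenceAmplicon)
  if (revComp(substr(referenceAmplicon, n - nchar(revPrimer) + 1L, n)) != revPrimer)
    stop("revPrimer is not the reverse complement of the amplicon 3' end", call. = FALSE)
  obj
}

#' @describeIn PlateLayout column (forward) barcodes, named by id
#' @param x a PlateLayout
#' @export
setMethod("columnBarcodes", "PlateLayout", function(x) x@columnBarcodes)
#' @describeIn PlateLayout row (reverse) barcodes, named by id
#' @export
setMethod("rowBarcodes", "PlateLayout", function(x) x@rowBarcodes)
#' @export
setMethod("fwdPrimer", "PlateLayout", function(x) x@fwdPrimer)
#' @export
setMethod("revPrimer", "PlateLayout", function(x) x@revPrimer)
#' @export
setMethod("referenceAmplicon", "PlateLayout", function(x) x@referenceAmplicon)
#' @describeIn PlateLayout 0-based cut-site offset in the reference amplicon
#' @export
setMethod("cutSite", "PlateLayout", function(x) x@cutSite)
#' @export
setMethod("flankSize", "PlateLayout", function(x) x@flank)

setMethod("show", "PlateLayout", function(object) {
  cat("PlateLayout:", length(object@columnBarcodes), "columns x",
      length(object@rowBarcodes), "rows =",
      length(object@columnBarcodes) * length(object@rowBarcodes), "wells\n")
  cat("  amplicon:", nchar(object@referenceAmplicon), "nt; cut site at",
      object@cutSite + 1L, "(1-based); flank", object@flank, "nt\n")
  cat("  primers:", nchar(object@fwdPrimer), "nt fwd /",
      nchar(object@revPrimer), "nt rev;",
      countPrimers(object), "barcoded oligos\n")
})

#' Enumerate well identities of a plate layout
#'
#' Wells are enumerated row-major (A1, A2, ... H12). Each well is identified
#' by a distinct (column barcode, row barcode) pair.
#'
#' @param layout a \linkS4class{PlateLayout}.
#' @return data.frame with columns \code{well}, \code{row_label},
#'   \code{column_label}, \code{column_barcode_id}, \code{row_barcode_id}.
#' @export
setMethod("enumerateWells", "PlateLayout", function(layout) {
  validObject(layout)
  nr <- length(layout@rowBarcodes)
  nc <- length(layout@columnBarcodes)
  rows <- LETTERS[seq_len(nr)]
  grid <- expand.grid(column = seq_len(nc), row = seq_len(nr),
                      KEEP.OUT.ATTRS = FALSE)
  ## expand.grid varies the first factor fastest -> row-major order A1..A12,B1..
  data.frame(
    well = .wellName(rows[grid$row], grid$column),
    row_label = rows[grid$row],
    column_label = grid$column,
    column_barcode_id = names(layout@columnBarcodes)[grid$column],
    row_barcode_id = names(layout@rowBarcodes)[grid$row],
    stringsAsFactors = FALSE)
})

#' Number of barcoded oligos needed for a layout
#'
#' One oligo per barcode: columns + rows. The target-specific portion is
#' shared, so 12 + 8 = 20 oligos index 96 wells (versus 96 per-well fusion
#' primers).
#'
#' @param layout a \linkS4class{PlateLayout}.
#' @return integer oligo count.
#' @export
setMethod("countPrimers", "PlateLayout", function(layout) {
  length(layout@columnBarcodes) + length(layout@rowBarcodes)
})

#' Length of the reference amplicon
#' @param layout a \linkS4class{PlateLayout}.
#' @return integer; equals 2 x flank when the amplicon was designed with equal
#'   flanks either side of the guide.
#' @export
setMethod("expectedAmpliconLength", "PlateLayout", function(layout) {
  nchar(layout@referenceAmplicon)
})

#' Screen a barcode set for confusable pairs
#'
#' Reports the minimum pairwise distance (Hamming for equal-length pairs,
#' edit distance otherwise) and flags all pairs below \code{minDistance}.
#' A minimum distance of at least \code{2*m + 1} guarantees that demultiplexing
#' with up to \code{m} tolerated mismatches can never assign an error-free
#' read ambiguously.
#'
#' @param barcodes named character vector of barcode sequences.
#' @param minDistance required minimum pairwise distance (default 3, which
#'   supports 1-mismatch demultiplexing).
#' @return list with \code{min_distance} (Inf for a singleton set),
#'   \code{pass} (logical), and \code{flagged} (data.frame of offending pairs).
#' @export
validateBarcodeSet <- function(barcodes, minDistance = 3L) {
  if (length(barcodes) < 1) stop("empty barcode set", call. = FALSE)
  if (is.null(names(barcodes))) names(barcodes) <- paste0("bc", seq_along(barcodes))
  if (!all(grepl("^[ACGT]+$", barcodes)))
    stop("barcodes must be A/C/G/T strings", call. = FALSE)
  flagged <- data.frame(id1 = character(0), id2 = character(0),
                        distance = integer(0), stringsAsFactors = FALSE)
  if (length(barcodes) == 1)
    return(list(min_distance = Inf, pass = TRUE, flagged = flagged))
  pairs <- combn(length(barcodes), 2)
  d <- apply(pairs, 2, function(ij) seqDistance(barcodes[[ij[1]]], barcodes[[ij[2]]]))
  bad <- which(d < minDistance)
  if (length(bad)) {
    flagged <- data.frame(
      id1 = names(barcodes)[pairs[1, bad]],
      id2 = names(barcodes)[pairs[2, bad]],
      distance = as.integer(d[bad]), stringsAsFactors = FALSE)
  }
  list(min_distance = min(d), pass = length(bad) == 0, flagged = flagged)
}

#' Write a plate map TSV
#'
#' One row per well with its row/column labels and barcode pair.
#'
#' @param layout a \linkS4class{PlateLayout}.
#' @param path output TSV path.
#' @return the well table, invisibly.
#' @export
writePlateMap <- function(layout, path) {
  wells <- enumerateWells(layout)
  wells$column_barcode <- columnBarcodes(layout)[wells$column_barcode_id]
  wells$row_barcode <- rowBarcodes(layout)[wells$row_barcode_id]
  write.table(wells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(wells)
}

#' Read a plate layout from a YAML config file
#'
#' The config lists the column and row barcodes (id: sequence maps), the
#' target-specific primers, the reference amplicon (inline string, or
#' \code{reference_fasta} path), the \emph{1-based} cut site and the design
#' flank. See \code{system.file("extdata", "example_layout.yaml",
#' package = "ampliclone")}.
#'
#' @param path YAML file path.
#' @return a \linkS4class{PlateLayout}.
#' @export
readPlateLayout <- function(path) {
  cfg <- yaml::read_yaml(path)
  amp <- cfg$reference_amplicon
  if (is.null(amp) && !is.null(cfg$reference_fasta)) {
    fa <- Biostrings::readDNAStringSet(file.path(dirname(path), cfg$reference_fasta))
    amp <- as.character(fa[[1]])
  }
  if (is.null(amp)) stop("config must give reference_amplicon or reference_fasta", call. = FALSE)
  PlateLayout(
    columnBarcodes = unlist(cfg$column_barcodes),
    rowBarcodes = unlist(cfg$row_barcodes),
    fwdPrimer = cfg$fwd_primer, revPrimer = cfg$rev_primer,
    referenceAmplicon = amp, cutSite = cfg$cut_site,
    flank = if (is.null(cfg$flank)) NULL else cfg$flank)
}

#' Write a plate layout to a YAML config file
#' @param layout a \linkS4class{PlateLayout}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePlateLayout <- function(layout, path) {
  cfg <- list(
    column_barcodes = as.list(columnBarcodes(layout)),
    row_barcodes = as.list(rowBarcodes(layout)),
    fwd_primer = fwdPrimer(layout),
    rev_primer = revPrimer(layout),
    reference_amplicon = referenceAmplicon(layout),
    cut_site = cutSite(layout) + 1L,
    flank = flankSize(layout))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

## Placeholder 10 nt barcodes, pairwise Hamming distance >= 5 across the whole
## set so that 1-mismatch demultiplexing can never cross-assign a read.
.EXAMPLE_COLUMN_BC <- c(
  C01 = "AAATTACCCG", C02 = "AGAACTCCGC", C03 = "GGTGTAGCTG", C04 = "GATGTCCTGA",
  C05 = "AACCTAAGAG", C06 = "CTGCTTATCG", C07 = "TCCGTTCTTC", C08 = "CGGAGAAGCG",
  C09 = "ATTGGGCGAT", C10 = "AGGGTCTAAG", C11 = "CGTTTGATCT", C12 = "GACAGTCGTC")
.EXAMPLE_ROW_BC <- c(
  R01 = "TTGCGTTTAA", R02 = "GAAACCATTT", R03 = "TTGTTGACTT", R04 = "ACGAGGTACT",
  R05 = "AGCATCTTGA", R06 = "CACCGGTTGA", R07 = "TGACTGGTAC", R08 = "CGCCCGACGT")

## 200 nt synthetic reference amplicon: guide cut site at the centre
## (offset 100, 0-based), 100 nt flank either side, 20 nt primer sites at the
## ends. Contains several homopolymer runs (one straddling the cut site) so
## that indel left-alignment and the homopolymer error model are exercised.
.EXAMPLE_AMPLICON <- paste0(
  "CGGCGGAGAGGAGACTATCATATGACCAGCACTGCCGATCTTCGTCGGTG",
  "CCTCACTAAAAGCAGTTCAGTTGGAGTAGAATACCTTGATAGGCATTTTT",
  "GGTGCCCATGCCCTTGTCCCTATGCCTACCATAGTGTGGAGCTCTTCGCA",
  "ATTCGTGCGGGGGGTTGTAACGTAATTTGACTACGCATACATAAGTGATA")

#' The packaged example plate layout
#'
#' A synthetic 96-well screen: 12 column + 8 row placeholder barcodes (10 nt,
#' pairwise Hamming distance >= 5), 20 nt target primers, and a 200 nt
#' synthetic reference amplicon with the cut site at its centre (flank 100 nt
#' either side of the guide). Smaller plates are obtained by subsetting
#' \code{columns}/\code{rows}.
#'
#' @param columns,rows number of plate columns (<= 12) and rows (<= 8).
#' @return a \linkS4class{PlateLayout}.
#' @examples
#' layout <- exampleLayout()
#' nrow(enumerateWells(layout))  # 96
#' countPrimers(layout)          # 20
#' @export
exampleLayout <- function(columns = 12L, rows = 8L) {
  stopifnot(columns >= 1, columns <= 12, rows >= 1, rows <= 8)
  amp <- .EXAMPLE_AMPLICON
  PlateLayout(
    columnBarcodes = .EXAMPLE_COLUMN_BC[seq_len(columns)],
    rowBarcodes = .EXAMPLE_ROW_BC[seq_len(rows)],
    fwdPrimer = substr(amp, 1L, 20L),
    revPrimer = revComp(substr(amp, nchar(amp) - 19L, nchar(amp))),
    referenceAmplicon = amp,
    cutSite = 101L,  # 1-based constructor convention -> 0-based offset 100
    flank = 100L)
}
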