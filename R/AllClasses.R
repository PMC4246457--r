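#' PlateLayout: barcode/primer/reference geometry of a combinatorial screen
#'
#' Describes the row/column barcoded fusion-primer scheme: up to 12 column
#' (forward) barcodes and 8 row (reverse) barcodes index up to 96 wells by the
#' barcode \emph{pair}. The reference amplicon spans the target-specific
#' primers and the CRISPR cut site; \code{cutSite} is the 0-based offset of
#' the expected double-strand break in the reference amplicon.
#'
#' @slot columnBarcodes named character vector (names = barcode ids) of
#'   column/forward barcode sequences, plate columns 1..12 in order.
#' @slot rowBarcodes named character vector of row/reverse barcode sequences,
#'   plate rows A..H in order.
#' @slot fwdPrimer,revPrimer target-specific primer sequences (~20 nt); the
#'   forward primer is the 5' end of the reference amplicon and the reverse
#'   primer is the reverse complement of its 3' end.
#' @slot referenceAmplicon the amplified reference sequence (~200 nt).
#' @slot cutSite 0-based offset of the expected cut site in the amplicon.
#' @slot flank nucleotides covered either side of the guide site (design
#'   record only; 100 in the packaged example, giving a 200 bp amplicon).
#'
#' @export
setClass("PlateLayout", representation(
  columnBarcodes  = "character",
  rowBarcodes     = "character",
  fwdPrimer       = "character",
  revPrimer       = "character",
  referenceAmplicon = "character",
  cutSite         = "integer",
  flank           = "integer"
))

setValidity("PlateLayout", function(object) {
  msg <- character(0)
  chk_bc <- function(bc, role, maxn) {
    m <- character(0)
    if (length(bc) < 1) m <- c(m, paste0("need at least one ", role, " barcode"))
    if (length(bc) > maxn) m <- c(m, paste0("at most ", maxn, " ", role, " barcodes supported"))
    if (is.null(names(bc)) || anyDuplicated(names(bc)))
      m <- c(m, paste0(role, " barcode ids must be unique and non-empty"))
    if (!all(grepl("^[ACGT]+$", bc)))
      m <- c(m, paste0(role, " barcodes must be A/C/G/T strings"))
    if (anyDuplicated(bc))
      m <- c(m, paste0("duplicate ", role, " barcode sequence"))
    m
  }
  msg <- c(msg, chk_bc(object@columnBarcodes, "column", 12L))
  msg <- c(msg, chk_bc(object@rowBarcodes, "row", 8L))
  if (!.isDNA(object@referenceAmplicon)) msg <- c(msg, "referenceAmplicon must be an A/C/G/T string")
  if (!.isDNA(object@fwdPrimer)) msg <- c(msg, "fwdPrimer must be an A/C/G/T string")
  if (!.isDNA(object@revPrimer)) msg <- c(msg, "revPrimer must be an A/C/G/T string")
  if (length(msg) == 0) {
    if (object@cutSite < 0L || object@cutSite >= nchar(object@referenceAmplicon))
      msg <- c(msg, "cutSite must lie within the reference amplicon")
    if (nchar(object@referenceAmplicon) < nchar(object@fwdPrimer) + nchar(object@revPrimer))
      msg <- c(msg, "reference amplicon shorter than the two primers combined")
  }
  if (length(msg)) msg else TRUE
})

#' DemuxParams: tolerances for dual-barcode read assignment
#'
#' @slot maxMismatch maximum substitutions tolerated per barcode (default 1).
#' @slot requireBothBarcodes must both the leading and trailing barcode be
#'   recognized for assignment (default TRUE; the well identity is the pair).
#' @slot minReadLength reads shorter than this are unassigned as "too_short".
#' @slot endSlop bases of 3'-trimming slop tolerated when anchoring the
#'   trailing barcode to the read end (default 2).
#' @export
setClass("DemuxParams", representation(
  maxMismatch = "integer",
  requireBothBarcodes = "logical",
  minReadLength = "integer",
  endSlop = "integer"
))

setValidity("DemuxParams", function(object) {
  msg <- character(0)
  if (object@maxMismatch < 0L) msg <- c(msg, "maxMismatch must be >= 0")
  if (object@minReadLength < 0L) msg <- c(msg, "minReadLength must be >= 0")
  if (object@endSlop < 0L) msg <- c(msg, "endSlop must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ScoringScheme: affine-gap scores for glocal amplicon alignment
#'
#' Alignment is global in the read and local in the reference (reference
#' overhangs are free). A gap of length L costs \code{gapOpen + L * gapExtend},
#' mirroring read-gap penalties of the form "open 5, extend 1" that keep a
#' 10-50 nt cut-site deletion as a single gap instead of shredding it.
#'
#' @slot match match score (positive).
#' @slot mismatch mismatch penalty (subtracted; >= 0).
#' @slot gapOpen gap opening penalty (>= 0).
#' @slot gapExtend per-base gap extension penalty (>= 0, <= gapOpen).
#' @slot minScoreFrac alignments scoring below
#'   \code{minScoreFrac * match * nchar(read)} are reported unaligned.
#' @export
setClass("ScoringScheme", representation(
  match = "integer",
  mismatch = "integer",
  gapOpen = "integer",
  gapExtend = "integer",
  minScoreFrac = "numeric"
))

setValidity("ScoringScheme", function(object) {
  msg <- character(0)
  if (object@match <= 0L) msg <- c(msg, "match score must be positive")
  if (object@mismatch < 0L || object@gapOpen < 0L || object@gapExtend < 0L)
    msg <- c(msg, "penalties must be >= 0")
  if (object@gapExtend > object@gapOpen)
    msg <- c(msg, "gapExtend must not exceed gapOpen")
  if (length(msg)) msg else TRUE
})
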