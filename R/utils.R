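## Small sequence helpers shared across modules. Coordinates are 0-based
## half-open everywhere inside the package; user-facing reports are 1-based.

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T, upper case).
#' @return character vector of the same length.
#' @export
revComp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.isDNA <- function(x) {
  length(x) == 1 && is.character(x) && !is.na(x) && grepl("^[ACGT]+$", x)
}

.assertDNA <- function(x, what) {
  if (!.isDNA(x)) stop(what, " must be a non-empty A/C/G/T string", call. = FALSE)
  invisible(x)
}

#' Hamming distance between equal-length strings
#'
#' Edit distance (via \code{adist}) is used when lengths differ, so that
#' barcode sets of unequal length can still be screened for confusability.
#'
#' @param a,b single DNA strings.
#' @return integer distance.
#' @export
seqDistance <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  } else {
    as.integer(utils::adist(a, b))
  }
}

## row label "A".."H" + column number -> "A1".."H12"
.wellName <- function(row_label, column_label) paste0(row_label, column_label)

## fixed quality character used for simulated reads (phred 40, Sanger +33)
.SIM_QUAL <- "I"
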