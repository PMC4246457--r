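#' Classify the zygosity of one well
#'
#' Maps the called allele composition onto the five screening classes.
#' Wildtype counts as an allele when deciding whether a well shows "more than
#' two different alleles": a true diploid clone cannot carry three, so any
#' third called allele marks a mixed well.
#'
#' \itemize{
#'   \item wildtype only -> \code{WILDTYPE}
#'   \item wildtype + one mutant -> \code{HETEROZYGOUS}
#'   \item one mutant, no wildtype -> \code{HOMOZYGOUS}
#'   \item two distinct mutants, no wildtype -> \code{COMPOUND_HETEROZYGOUS}
#'   \item more than two called alleles -> \code{MIXED}
#'   \item nothing called -> \code{NO_CALL}
#' }
#'
#' @param alleles called allele data.frame from
#'   \code{\link{callWellAlleles}} (needs an \code{is_wildtype} column), or a
#'   logical vector \code{is_wildtype} per called allele.
#' @param minorEvidence logical; sub-threshold minor alleles were seen. Does
#'   not change the class (the clone may just need re-streaking) but is
#'   carried into reports.
#' @return one of "WILDTYPE", "HETEROZYGOUS", "HOMOZYGOUS",
#'   "COMPOUND_HETEROZYGOUS", "MIXED", "NO_CALL".
#' @export
classifyGenotype <- function(alleles, minorEvidence = FALSE) {
  isWt <- if (is.data.frame(alleles)) alleles$is_wildtype else as.logical(alleles)
  nAll <- length(isWt)
  nWt <- sum(isWt)
  nMut <- nAll - nWt
  if (nAll == 0) return("NO_CALL")
  if (nAll > 2) return("MIXED")
  if (nMut == 0) return("WILDTYPE")
  if (nWt >= 1) return("HETEROZYGOUS")          # wt + 1 mutant
  if (nMut == 1) return("HOMOZYGOUS")
  "COMPOUND_HETEROZYGOUS"                       # two distinct mutants
}

.GENO_CLASSES <- c("WILDTYPE", "HETEROZYGOUS", "HOMOZYGOUS",
                   "COMPOUND_HETEROZYGOUS", "MIXED", "NO_CALL")

#' Summarize a cohort of genotype calls
#'
#' Tallies the five classes plus NO_CALL and derives the screening
#' headline numbers: the biallelic-disruption count (homozygous plus compound
#' heterozygous — both alleles carry a mutation) and the mutated count under
#' two conventions. \code{mutated_including_nocall} treats every non-wildtype
#' well (including unmapped ones) as showing genetic insult, i.e.
#' total - wildtype; \code{mutated_excluding_nocall} restricts both numerator
#' and denominator (\code{callable}) to wells that could be called.
#'
#' @param calls character vector of classes, or a data.frame with a
#'   \code{class} column (as from \code{\link{runPipeline}}).
#' @return list: \code{counts} (named, all six classes), \code{total},
#'   \code{callable}, \code{biallelic_disrupted},
#'   \code{mutated_including_nocall}, \code{mutated_excluding_nocall},
#'   \code{mutation_rate} (excluding-no-call convention).
#' @export
summarizeCohort <- function(calls) {
  cls <- if (is.data.frame(calls)) calls$class else as.character(calls)
  if (length(cls) && !all(cls %in% .GENO_CLASSES))
    stop("unknown genotype class: ",
         paste(setdiff(cls, .GENO_CLASSES), collapse = ", "), call. = FALSE)
  counts <- table(factor(cls, levels = .GENO_CLASSES))
  counts <- stats::setNames(as.integer(counts), .GENO_CLASSES)
  total <- length(cls)
  callable <- total - counts[["NO_CALL"]]
  biallelic <- counts[["HOMOZYGOUS"]] + counts[["COMPOUND_HETEROZYGOUS"]]
  mutatedEx <- callable - counts[["WILDTYPE"]]
  mutatedIn <- total - counts[["WILDTYPE"]]
  list(counts = counts, total = total, callable = callable,
       biallelic_disrupted = biallelic,
       mutated_including_nocall = mutatedIn,
       mutated_excluding_nocall = mutatedEx,
       mutation_rate = if (callable > 0) mutatedEx / callable else NA_real_)
}

#' Frameshift annotation for an allele signature
#'
#' The net indel length of the allele modulo 3 decides the reading-frame
#' consequence: non-zero is a frameshift. Substitution-only alleles are
#' in-frame; the wildtype allele is "n/a", as is every allele when no coding
#' frame applies to the amplicon.
#'
#' @param signature a signature string from \code{\link{extractAlleles}}.
#' @param hasFrame does a coding frame apply (default TRUE); pass FALSE when
#'   the amplicon is non-coding.
#' @return "frameshift", "in-frame" or "n/a".
#' @export
annotateFrameshift <- function(signature, hasFrame = TRUE) {
  if (!hasFrame || identical(signature, "WT")) return("n/a")
  ks <- strsplit(signature, ";")[[1]]
  net <- 0L
  for (k in ks) {
    p <- strsplit(k, ":")[[1]]
    if (p[1] == "D") net <- net - as.integer(p[3])
    if (p[1] == "I") net <- net + as.integer(p[3])
  }
  if (net %% 3L != 0L) "frameshift" else "in-frame"
}
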