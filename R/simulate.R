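## Synthetic screening runs with full ground truth.
##
## Reads are built exactly the way the library is built on the bench:
## column barcode + forward primer + (allele-modified amplicon core) +
## rc(reverse primer) + rc(row barcode), emitted in plus or minus orientation
## with probability 1/2 each. On top of the clean read the simulator layers
## the platform's error phenomenology: uniform substitution errors,
## length-dependent +-1 homopolymer indels, barcode-region errors, and
## strand-restricted recurrent artifacts at fixed reference positions.

## ---- allele specs --------------------------------------------------------

#' Allele specifications for the simulator
#'
#' An allele is the wildtype amplicon or the amplicon carrying one variant at
#' a cut-site-relative offset: \code{offset} is 0-based relative to the cut
#' site (0 = the cut-site base itself; negative = 5' of it). Deletions start
#' at \code{cut + offset}; insertions are inserted before \code{cut + offset};
#' substitutions replace the base at \code{cut + offset}.
#'
#' @param length deletion length (nt).
#' @param offset 0-based offset from the cut site.
#' @param seq inserted sequence.
#' @param base replacement base.
#' @return an allele spec list with a \code{label} field.
#' @name alleleSpecs
NULL

#' @rdname alleleSpecs
#' @export
alleleWildtype <- function() {
  list(kind = "wildtype", label = "WT")
}

#' @rdname alleleSpecs
#' @export
alleleDeletion <- function(length, offset = 0L) {
  stopifnot(length >= 1)
  list(kind = "deletion", length = as.integer(length), offset = as.integer(offset),
       label = paste0("del", length, "@", offset))
}

#' @rdname alleleSpecs
#' @export
alleleInsertion <- function(seq, offset = 0L) {
  .assertDNA(seq, "inserted sequence")
  list(kind = "insertion", length = nchar(seq), seq = seq,
       offset = as.integer(offset),
       label = paste0("ins", nchar(seq), seq, "@", offset))
}

#' @rdname alleleSpecs
#' @export
alleleSubstitution <- function(base, offset = 0L) {
  stopifnot(base %in% c("A", "C", "G", "T"))
  list(kind = "substitution", length = 1L, base = base,
       offset = as.integer(offset),
       label = paste0("sub", base, "@", offset))
}

## apply one allele spec to the amplicon; returns the modified sequence
.applyAllele <- function(amp, cut, spec) {
  n <- nchar(amp)
  p <- cut + (spec$offset %||% 0L)  # 0-based
  switch(spec$kind,
    wildtype = amp,
    deletion = {
      stopifnot(p >= 0, p + spec$length <= n)
      paste0(substr(amp, 1L, p), substr(amp, p + spec$length + 1L, n))
    },
    insertion = {
      stopifnot(p >= 0, p <= n)
      paste0(substr(amp, 1L, p), spec$seq, substr(amp, p + 1L, n))
    },
    substitution = {
      stopifnot(p >= 0, p < n)
      paste0(substr(amp, 1L, p), spec$base, substr(amp, p + 2L, n))
    },
    stop("unknown allele kind: ", spec$kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## map a wildtype-amplicon position through an allele's single variant
.mapPosition <- function(pos, cut, spec) {
  if (spec$kind == "wildtype" || spec$kind == "substitution") return(pos)
  p <- cut + spec$offset
  if (spec$kind == "deletion") {
    if (pos < p) pos else if (pos < p + spec$length) NA_integer_ else pos - spec$length
  } else {                                  # insertion
    if (pos < p) pos else pos + spec$length
  }
}

## ---- configuration -------------------------------------------------------

#' Configure a simulated screening run
#'
#' Defaults model the pooled Ion-Torrent-style amplicon screen the package
#' targets: lognormal per-well depth (mean 2455x, sigma 0.7, spanning roughly
#' 300x-6600x), 1\% per-base substitution error, length-dependent homopolymer
#' indels, and barcode-region errors at the substitution rate.
#'
#' @param layout a \linkS4class{PlateLayout}.
#' @param wellConfigs named list (well name -> list with \code{alleles} = list
#'   of allele specs, \code{fractions} summing to 1, optional fixed
#'   \code{depth}, optional \code{true_class} override).
#' @param meanDepth mean of the lognormal per-well depth model.
#' @param depthSigma lognormal sigma (log scale).
#' @param substitutionRate per-base substitution error rate in the amplicon.
#' @param homopolymerIndelRate base rate of +-1 indels per homopolymer run:
#'   a run of length L >= 3 gains/loses one base with probability
#'   \code{min(rate * (L - 2), 0.1)}.
#' @param barcodeErrorRate per-base substitution rate within barcode regions.
#' @param artifacts list of strand-restricted recurrent artifacts, each a
#'   list: \code{position} (0-based wildtype-amplicon offset), \code{kind}
#'   ("substitution"/"insertion"/"deletion"), \code{orientation}
#'   ("plus"/"minus"), \code{wells} (character vector), \code{prob} (fraction
#'   of affected-orientation reads carrying it, default 0.8), \code{base}
#'   (substituted/inserted base).
#' @return a \code{SimConfig} list.
#' @export
simConfig <- function(layout, wellConfigs, meanDepth = 2455, depthSigma = 0.7,
                      substitutionRate = 0.01, homopolymerIndelRate = 0.01,
                      barcodeErrorRate = 0.01, artifacts = list()) {
  validObject(layout)
  wells <- enumerateWells(layout)$well
  stopifnot(length(wellConfigs) >= 1, !is.null(names(wellConfigs)))
  if (!all(names(wellConfigs) %in% wells))
    stop("unknown wells in config: ",
         paste(setdiff(names(wellConfigs), wells), collapse = ", "), call. = FALSE)
  for (w in names(wellConfigs)) {
    wc <- wellConfigs[[w]]
    if (length(wc$alleles) != length(wc$fractions))
      stop("well ", w, ": alleles and fractions differ in length", call. = FALSE)
    if (abs(sum(wc$fractions) - 1) > 1e-8)
      stop("well ", w, ": fractions must sum to 1", call. = FALSE)
  }
  rates <- c(substitutionRate, homopolymerIndelRate, barcodeErrorRate)
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)", call. = FALSE)
  structure(list(layout = layout, wellConfigs = wellConfigs,
                 meanDepth = meanDepth, depthSigma = depthSigma,
                 substitutionRate = substitutionRate,
                 homopolymerIndelRate = homopolymerIndelRate,
                 barcodeErrorRate = barcodeErrorRate,
                 artifacts = artifacts),
            class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", length(x$wellConfigs), "wells | depth ~ lognormal(mean",
      x$meanDepth, ", sigma", x$depthSigma, ") | sub", x$substitutionRate,
      "| hp-indel", x$homopolymerIndelRate, "| barcode-err",
      x$barcodeErrorRate, "|", length(x$artifacts), "artifacts\n")
  invisible(x)
}

## ---- read generation -----------------------------------------------------

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

## homopolymer runs of length >= 3 in a sequence: data.frame(start0, len, base)
.hpRuns <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= 3
  data.frame(start0 = (ends - r$lengths)[keep], len = r$lengths[keep],
             base = r$values[keep], stringsAsFactors = FALSE)
}

#' Simulate a pooled screening run
#'
#' Fully reproducible from \code{seed}: identical seed and configuration give
#' byte-identical reads and truth tables.
#'
#' @param config a \code{SimConfig} from \code{\link{simConfig}}.
#' @param seed integer RNG seed.
#' @param fastqPath optional path: write the pooled reads as FASTQ (fixed
#'   phred-40 qualities).
#' @param truthPath optional path: write the per-read truth as TSV.
#' @return list: \code{reads} (named character vector, pooled across wells),
#'   \code{truth} (data.frame read_id, well, orientation, allele_label),
#'   \code{wells} (data.frame well, depth, true_class, alleles).
#' @export
simulateRun <- function(config, seed = 1L, fastqPath = NULL, truthPath = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(as.integer(seed))
  layout <- config$layout
  amp <- referenceAmplicon(layout)
  cut <- cutSite(layout)
  wells <- enumerateWells(layout)
  bcCol <- columnBarcodes(layout)
  bcRow <- rowBarcodes(layout)
  meanlog <- log(config$meanDepth) - config$depthSigma^2 / 2

  allReads <- character(0); allIds <- character(0)
  truthRows <- vector("list", length(config$wellConfigs))
  wellRows <- vector("list", length(config$wellConfigs))

  for (wi in seq_along(config$wellConfigs)) {
    w <- names(config$wellConfigs)[wi]
    wc <- config$wellConfigs[[w]]
    wrow <- wells[wells$well == w, ]
    bcF <- bcCol[[wrow$column_barcode_id]]
    bcRrc <- revComp(bcRow[[wrow$row_barcode_id]])
    depth <- if (!is.null(wc$depth)) as.integer(wc$depth) else
      max(1L, as.integer(round(rlnorm(1, meanlog, config$depthSigma))))
    k <- length(wc$alleles)
    alleleAmps <- lapply(wc$alleles, function(a) .applyAllele(amp, cut, a))
    alleleChars <- lapply(alleleAmps, function(s) strsplit(s, "")[[1]])
    alleleRuns <- lapply(alleleAmps, .hpRuns)
    labels <- vapply(wc$alleles, `[[`, "", "label")
    arts <- Filter(function(a) w %in% a$wells, config$artifacts)
    artMapped <- lapply(arts, function(a)
      lapply(wc$alleles, function(sp) .mapPosition(a$position, cut, sp)))

    origin <- sample.int(k, depth, replace = TRUE, prob = wc$fractions)
    ori <- ifelse(runif(depth) < 0.5, "plus", "minus")
    reads <- character(depth)
    bcFc <- strsplit(bcF, "")[[1]]
    bcRc <- strsplit(bcRrc, "")[[1]]
    nF <- length(bcFc)

    for (r in seq_len(depth)) {
      ai <- origin[r]
      chars <- alleleChars[[ai]]
      ## strand-restricted recurrent artifacts
      for (j in seq_along(arts)) {
        a <- arts[[j]]
        if (ori[r] != a$orientation) next
        p <- artMapped[[j]][[ai]]
        if (is.na(p) || runif(1) >= (a$prob %||% 0.8)) next
        if (a$kind == "substitution") {
          chars[p + 1L] <- a$base
        } else if (a$kind == "deletion") {
          chars <- chars[-(p + 1L)]
        } else {
          chars <- append(chars, a$base, after = p)
        }
      }
      ## homopolymer +-1 indels (length-dependent, capped)
      runs <- alleleRuns[[ai]]
      if (nrow(runs)) {
        pHit <- pmin(config$homopolymerIndelRate * (runs$len - 2L), 0.1)
        hit <- which(runif(nrow(runs)) < pHit)
        for (h in rev(hit)) {             # edit right-to-left
          pos <- runs$start0[h] + 1L      # 1-based run start
          if (runif(1) < 0.5) chars <- append(chars, runs$base[h], after = pos)
          else chars <- chars[-pos]
        }
      }
      full <- c(bcFc, chars, bcRc)
      n <- length(full)
      ## substitution errors: barcode regions vs amplicon core
      rate <- rep.int(config$substitutionRate, n)
      rate[seq_len(nF)] <- config$barcodeErrorRate
      rate[(n - length(bcRc) + 1L):n] <- config$barcodeErrorRate
      errAt <- which(runif(n) < rate)
      for (e in errAt)
        full[e] <- sample(.BASES[.BASES != full[e]], 1L)
      if (ori[r] == "minus") full <- rev(unname(.COMP[full]))
      reads[r] <- paste(full, collapse = "")
    }
    ids <- sprintf("%s_r%05d", w, seq_len(depth))
    allReads <- c(allReads, reads); allIds <- c(allIds, ids)
    truthRows[[wi]] <- data.frame(read_id = ids, well = w, orientation = ori,
                                  allele_label = labels[origin],
                                  stringsAsFactors = FALSE)
    trueClass <- wc$true_class %||%
      classifyGenotype(vapply(wc$alleles, function(a) a$kind == "wildtype",
                              logical(1)))
    wellRows[[wi]] <- data.frame(well = w, depth = depth,
                                 true_class = trueClass,
                                 alleles = paste(labels, collapse = ","),
                                 stringsAsFactors = FALSE)
  }
  names(allReads) <- allIds
  truth <- do.call(rbind, truthRows)
  wellsDf <- do.call(rbind, wellRows)
  if (!is.null(fastqPath)) {
    x <- Biostrings::DNAStringSet(allReads)
    q <- Biostrings::BStringSet(vapply(nchar(allReads), strrep, character(1),
                                       x = .SIM_QUAL))
    Biostrings::writeXStringSet(x, fastqPath, format = "fastq", qualities = q)
  }
  if (!is.null(truthPath))
    write.table(truth, truthPath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(reads = allReads, truth = truth, wells = wellsDf)
}

## ---- the reference cohort ------------------------------------------------

## draw a random mutant allele spec: deletion or insertion, 1-30 nt,
## overlapping the cut site; `used` holds labels to avoid within-well clashes
.randomMutantAllele <- function(used) {
  repeat {
    if (runif(1) < 0.6) {
      len <- sample.int(30L, 1L)
      off <- -sample.int(min(len, 20L), 1L) + 1L   # start in [cut-19, cut]
      a <- alleleDeletion(len, off)
    } else {
      len <- sample.int(30L, 1L)
      sq <- paste(sample(.BASES, len, replace = TRUE), collapse = "")
      a <- alleleInsertion(sq, sample(-5:5, 1L))
    }
    if (!(a$label %in% used)) return(a)
  }
}

#' Build the 67-clone screening cohort configuration
#'
#' Emits a simulated screen matching the composition observed in a full-plate
#' CRISPR-Cas9 clone screen: 67 occupied wells with 10 homozygous mutants, 27
#' compound heterozygotes, 4 heterozygotes, 2 wildtypes and 21 mixed clones,
#' plus 3 wells at sub-threshold depth that cannot be called. Mutant alleles
#' are random 1-30 nt indels overlapping the cut site; mixed wells carry
#' three distinct alleles at roughly equal fractions (what a two-founder-cell
#' well looks like). Two strand-restricted recurrent artifacts are injected
#' outside the cut-site window so the artifact filter has real targets.
#'
#' @param seed RNG seed for composing the cohort (the run itself is seeded in
#'   \code{\link{simulateRun}}).
#' @param layout a \linkS4class{PlateLayout} (default \code{exampleLayout()}).
#' @param depth mean per-well depth (default 1000).
#' @param counts named integer vector giving the class composition; the
#'   default is the screen condition above, totalling 67 wells.
#' @param ... further arguments to \code{\link{simConfig}}.
#' @return a \code{SimConfig}.
#' @export
makeScreenCohort <- function(seed = 1L, layout = exampleLayout(), depth = 1000,
                             counts = c(HOMOZYGOUS = 10L,
                                        COMPOUND_HETEROZYGOUS = 27L,
                                        HETEROZYGOUS = 4L,
                                        WILDTYPE = 2L,
                                        MIXED = 21L,
                                        NO_CALL = 3L), ...) {
  set.seed(as.integer(seed))
  wells <- enumerateWells(layout)$well
  nWells <- sum(counts)
  stopifnot(nWells <= length(wells))
  classes <- sample(rep(names(counts), counts))   # shuffle over the plate
  occupied <- wells[seq_len(nWells)]

  wellConfigs <- vector("list", nWells)
  names(wellConfigs) <- occupied
  for (i in seq_len(nWells)) {
    cl <- classes[i]
    used <- character(0)
    mut <- function() {
      a <- .randomMutantAllele(used)
      used <<- c(used, a$label)
      a
    }
    wc <- switch(cl,
      WILDTYPE = list(alleles = list(alleleWildtype()), fractions = 1),
      NO_CALL = list(alleles = list(alleleWildtype()), fractions = 1,
                     depth = 30L, true_class = "NO_CALL"),
      HOMOZYGOUS = list(alleles = list(mut()), fractions = 1),
      HETEROZYGOUS = list(alleles = list(alleleWildtype(), mut()),
                          fractions = c(0.5, 0.5)),
      COMPOUND_HETEROZYGOUS = list(alleles = list(mut(), mut()),
                                   fractions = c(0.5, 0.5)),
      MIXED = {
        if (runif(1) < 0.5)
          list(alleles = list(alleleWildtype(), mut(), mut()),
               fractions = c(0.34, 0.33, 0.33))
        else
          list(alleles = list(mut(), mut(), mut()),
               fractions = c(0.34, 0.33, 0.33))
      })
    wellConfigs[[i]] <- wc
  }

  amp <- referenceAmplicon(layout)
  subAlt <- function(p) .BASES[.BASES != substr(amp, p + 1L, p + 1L)][1]
  artifacts <- list(
    list(position = 30L, kind = "substitution", base = subAlt(30L),
         orientation = "plus", wells = occupied[seq_len(nWells %/% 2)],
         prob = 0.8),
    list(position = 168L, kind = "deletion",
         orientation = "minus",
         wells = occupied[seq(2L, nWells, by = 3L)], prob = 0.8))
  simConfig(layout, wellConfigs, meanDepth = depth, depthSigma = 0.5,
            artifacts = artifacts, ...)
}
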