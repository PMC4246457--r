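## Allele-signature extraction and artifact filtering.
##
## A per-read allele signature is the ordered set of left-aligned variants
## inside the cut-site window; variants outside the window are candidate
## sequencing artifacts and never allele-defining. True CRISPR alleles map in
## roughly equal proportion to both read orientations, whereas platform
## artifacts show extreme strand bias and recur at the same position across
## wells — those two observations drive the automated filter.

## ---- per-read variant extraction ---------------------------------------

## Walk one alignment and list its variants (0-based, left-aligned upstream).
## Returns data.frame(kind, position, length, alt).
.alignmentVariants <- function(read, ref, ref_start, cigar) {
  v <- cpp_alignment_variants(read, ref, ref_start, cigar)
  data.frame(kind = c("substitution", "deletion", "insertion")[v$kind],
             position = v$position, length = v$length, alt = v$alt,
             stringsAsFactors = FALSE)
}

.variantKey <- function(v) {
  if (nrow(v) == 0) return(character(0))
  ifelse(v$kind == "substitution", paste0("S:", v$position, ":", v$alt),
  ifelse(v$kind == "deletion", paste0("D:", v$position, ":", v$length),
         paste0("I:", v$position, ":", v$length, ":", v$alt)))
}

## does each variant touch the cut-site window [cut - window, cut + window]?
## deletions count by reference-interval overlap (a long deletion spanning the
## cut is allele-defining even if its left-aligned start sits upstream).
.inWindow <- function(v, cut, window) {
  lo <- cut - window; hi <- cut + window
  start <- v$position
  end <- ifelse(v$kind == "deletion", v$position + v$length - 1L, v$position)
  end >= lo & start <= hi
}

#' Extract per-read allele signatures near the cut site
#'
#' Collapses each aligned read into its allele signature: the ordered,
#' left-aligned variants that touch the cut-site window (\code{cutSite(layout)
#' +/- window}). An empty signature ("WT") is the wildtype allele. Variants
#' outside the window are returned separately as candidate artifacts.
#'
#' @param alignments data.frame from \code{\link{alignReads}} with an
#'   \code{orientation} column; rows with \code{aligned == FALSE} count as
#'   unmapped.
#' @param layout a \linkS4class{PlateLayout}.
#' @param window half-width (nt) of the cut-site window (default 25).
#' @return list: \code{reads} (read_id, orientation, signature),
#'   \code{variants} (one row per distinct variant: key, kind, position,
#'   length, alt, in_window), \code{readVariants} (read_id x variant key,
#'   long form), \code{unmapped} (count).
#' @export
extractAlleles <- function(alignments, layout, window = 25L) {
  ref <- referenceAmplicon(layout)
  cut <- cutSite(layout)
  aln <- alignments[alignments$aligned, , drop = FALSE]
  unmapped <- sum(!alignments$aligned)
  if (nrow(aln) == 0) {
    return(list(
      reads = data.frame(read_id = character(0), orientation = character(0),
                         signature = character(0), stringsAsFactors = FALSE),
      variants = data.frame(key = character(0), kind = character(0),
                            position = integer(0), length = integer(0),
                            alt = character(0), in_window = logical(0),
                            stringsAsFactors = FALSE),
      readVariants = data.frame(read_id = character(0), key = character(0),
                                stringsAsFactors = FALSE),
      unmapped = unmapped))
  }
  if (is.null(aln$read_id)) aln$read_id <- paste0("read", seq_len(nrow(aln)))
  if (is.null(aln$orientation)) aln$orientation <- "plus"

  ## alignment (and hence variants) is a pure function of the sequence
  key <- paste(aln$read, aln$ref_start, aln$cigar)
  uniq <- !duplicated(key)
  uvar <- lapply(which(uniq), function(i) {
    v <- .alignmentVariants(aln$read[i], ref, aln$ref_start[i], aln$cigar[i])
    v$key <- .variantKey(v)
    v$in_window <- .inWindow(v, cut, window)
    v
  })
  names(uvar) <- key[uniq]
  sigOf <- vapply(uvar, function(v) {
    vin <- v[v$in_window, , drop = FALSE]
    if (nrow(vin) == 0) "WT" else
      paste(vin$key[order(vin$position, vin$kind, vin$length, vin$alt)],
            collapse = ";")
  }, character(1))

  readsDf <- data.frame(read_id = aln$read_id, orientation = aln$orientation,
                        signature = unname(sigOf[key]), stringsAsFactors = FALSE)
  rv <- do.call(rbind, lapply(seq_along(uvar), function(u) {
    v <- uvar[[u]]
    if (nrow(v) == 0) return(NULL)
    ids <- aln$read_id[key == names(uvar)[u]]
    data.frame(read_id = rep(ids, each = nrow(v)),
               key = rep(v$key, times = length(ids)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rv)) rv <- data.frame(read_id = character(0), key = character(0),
                                    stringsAsFactors = FALSE)
  allv <- do.call(rbind, uvar)
  vtab <- allv[!duplicated(allv$key),
               c("key", "kind", "position", "length", "alt", "in_window")]
  rownames(vtab) <- NULL
  list(reads = readsDf, variants = vtab, readVariants = rv, unmapped = unmapped)
}

## ---- strand bias --------------------------------------------------------

#' Exact binomial strand-bias test for a variant
#'
#' Tests whether the variant's plus-orientation fraction departs from the
#' well's overall plus fraction (two-sided exact binomial test). The variant
#' is declared biased only when the test rejects at \code{alpha} \emph{and}
#' its plus fraction is extreme (>= \code{extremity} or <= 1 - extremity):
#' the extremity guard carries most of the specificity, mirroring the visual
#' call that an artifact sits essentially on one strand only.
#'
#' @param plusCount,minusCount supporting reads by orientation.
#' @param wellPlusFraction the well's overall plus-read fraction.
#' @param alpha significance level (default 0.01, uncorrected).
#' @param extremity plus-fraction extremity threshold (default 0.9).
#' @return list with \code{p_value} and \code{biased}.
#' @export
strandBiasTest <- function(plusCount, minusCount, wellPlusFraction,
                           alpha = 0.01, extremity = 0.9) {
  n <- plusCount + minusCount
  if (n < 1) stop("need at least one supporting read", call. = FALSE)
  p0 <- min(max(wellPlusFraction, 1e-6), 1 - 1e-6)
  pv <- stats::binom.test(plusCount, n, p = p0,
                          alternative = "two.sided")$p.value
  frac <- plusCount / n
  biased <- (pv < alpha) && (frac >= extremity || frac <= 1 - extremity)
  list(p_value = pv, biased = biased)
}

## ---- cross-well recurrence ----------------------------------------------

#' Blacklist recurrent strand-biased artifact positions across wells
#'
#' Platform artifacts recur at the same reference position in many wells.
#' Any out-of-window, strand-biased variant observed at the same
#' \code{(position, kind)} in at least \code{minWells} wells is blacklisted.
#' In-window variants supported on both strands can never enter the
#' blacklist.
#'
#' @param wellVariants data.frame across wells with columns \code{well},
#'   \code{position}, \code{kind}, \code{in_window}, \code{biased} (one row
#'   per variant per well; see \code{\link{callWellAlleles}} output
#'   \code{$artifact_candidates}).
#' @param minWells minimum number of wells (default 3).
#' @return data.frame blacklist with columns \code{position}, \code{kind},
#'   \code{n_wells}.
#' @export
recurrenceFilter <- function(wellVariants, minWells = 3L) {
  empty <- data.frame(position = integer(0), kind = character(0),
                      n_wells = integer(0), stringsAsFactors = FALSE)
  if (is.null(wellVariants) || nrow(wellVariants) == 0) return(empty)
  cand <- wellVariants[!wellVariants$in_window & wellVariants$biased, ,
                       drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  keyw <- paste(cand$position, cand$kind)
  tab <- tapply(cand$well, keyw, function(w) length(unique(w)))
  hit <- names(tab)[tab >= minWells]
  if (length(hit) == 0) return(empty)
  parts <- strsplit(hit, " ")
  data.frame(position = as.integer(vapply(parts, `[`, "", 1)),
             kind = vapply(parts, `[`, "", 2),
             n_wells = as.integer(tab[hit]), stringsAsFactors = FALSE)
}

## ---- per-well allele calling --------------------------------------------

#' Call the alleles of one well with artifact filtering
#'
#' Collapses per-read signatures into well alleles: strand-biased or
#' blacklisted variants are removed from signatures first, identical
#' signatures are merged with summed counts, substitution-only signatures
#' must clear a stricter fraction and strand-balance bar (single-base errors
#' dominate the platform noise), and signatures below the minimum allele
#' fraction are dropped — those in the minor band are surfaced as evidence of
#' clonal mixedness.
#'
#' @param alignments data.frame from \code{\link{alignReads}} with
#'   \code{orientation} (and optionally \code{read_id}) columns for one well.
#' @param layout a \linkS4class{PlateLayout}.
#' @param window cut-site window half-width, nt (default 25).
#' @param minCoverage minimum aligned reads to call the well (default 100;
#'   below it the well is NO_CALL).
#' @param minAlleleFraction minimum fraction to call an allele (default 0.20).
#' @param minorFraction lower edge of the minor-evidence band (default 0.05);
#'   signatures in [minorFraction, minAlleleFraction) set
#'   \code{minor_allele_evidence}.
#' @param subOnlyMinFraction stricter call threshold for substitution-only
#'   alleles (default 0.25).
#' @param alpha,extremity strand-bias test parameters
#'   (see \code{\link{strandBiasTest}}).
#' @param blacklist recurrence blacklist from \code{\link{recurrenceFilter}}
#'   (optional).
#' @param minVariantReads variants below this support are reported
#'   low_support among artifact candidates (default 3).
#' @param extraction optional precomputed result of
#'   \code{\link{extractAlleles}} for these alignments (avoids re-extraction
#'   when calling in two passes).
#' @return list: \code{status} ("OK"/"NO_CALL"), \code{alleles} (signature,
#'   read_count, plus_count, minus_count, fraction, is_wildtype,
#'   substitution_only), \code{minor_allele_evidence} (logical),
#'   \code{minor} (sub-threshold signatures), \code{artifacts} (flagged
#'   variants with primary reason and evidence),
#'   \code{artifact_candidates} (all variant-level rows for
#'   \code{\link{recurrenceFilter}}), \code{stats} (input/aligned/unmapped/
#'   dropped read accounting and the well plus fraction).
#' @export
callWellAlleles <- function(alignments, layout, window = 25L,
                            minCoverage = 100L, minAlleleFraction = 0.20,
                            minorFraction = 0.05, subOnlyMinFraction = 0.25,
                            alpha = 0.01, extremity = 0.9,
                            blacklist = NULL, minVariantReads = 3L,
                            extraction = NULL) {
  ex <- extraction %||% extractAlleles(alignments, layout, window)
  nInput <- nrow(alignments)
  coverage <- nrow(ex$reads)
  stats <- list(input_reads = nInput, aligned = coverage,
                unmapped = ex$unmapped, dropped_minor = 0L,
                plus_fraction = NA_real_)
  emptyAll <- data.frame(signature = character(0), read_count = integer(0),
                         plus_count = integer(0), minus_count = integer(0),
                         fraction = numeric(0), is_wildtype = logical(0),
                         substitution_only = logical(0), stringsAsFactors = FALSE)
  if (coverage < minCoverage) {
    return(list(status = "NO_CALL", alleles = emptyAll,
                minor_allele_evidence = FALSE, minor = emptyAll,
                artifacts = NULL, artifact_candidates = NULL, stats = stats))
  }
  plusFrac <- mean(ex$reads$orientation == "plus")
  stats$plus_fraction <- plusFrac

  ## variant-level strand tallies
  rv <- merge(ex$readVariants,
              ex$reads[, c("read_id", "orientation")], by = "read_id")
  vstats <- if (nrow(rv)) {
    agg <- tapply(rv$orientation == "plus", rv$key,
                  function(x) c(plus = sum(x), n = length(x)))
    data.frame(key = names(agg),
               plus = vapply(agg, `[[`, 0, "plus"),
               n = vapply(agg, `[[`, 0, "n"),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(key = character(0), plus = numeric(0), n = numeric(0),
                    stringsAsFactors = FALSE)
  vtab <- merge(ex$variants, vstats, by = "key", all.x = TRUE)
  vtab$minus <- vtab$n - vtab$plus
  sb <- lapply(seq_len(nrow(vtab)), function(i)
    strandBiasTest(vtab$plus[i], vtab$minus[i], plusFrac, alpha, extremity))
  vtab$p_value <- vapply(sb, `[[`, 0, "p_value")
  vtab$biased <- vapply(sb, `[[`, TRUE, "biased")
  vtab$blacklisted <- rep(FALSE, nrow(vtab))
  if (!is.null(blacklist) && nrow(blacklist)) {
    vtab$blacklisted <- paste(vtab$position, vtab$kind) %in%
      paste(blacklist$position, blacklist$kind)
    ## guard: never blacklist an in-window variant supported on both strands
    vtab$blacklisted[vtab$in_window & vtab$plus > 0 & vtab$minus > 0] <- FALSE
  }

  ## sporadic sequencing errors: variants supported by too few reads to be a
  ## real allele component (an allele component rides at the allele fraction,
  ## >= minAlleleFraction; stray errors sit near the per-base error rate).
  ## Stripping them before collapsing returns error-carrying reads to their
  ## parent allele, which is what visual inspection does implicitly.
  vtab$low_support <- (!vtab$in_window & vtab$n < minVariantReads) |
    (vtab$in_window & vtab$n / coverage < minorFraction)

  ## error correction for inserted sequences: a sequencing error inside an
  ## insertion changes its inserted bases but not its placement or length, so
  ## a low-support insertion co-located with a major same-length insertion is
  ## that allele plus a read error — remap it instead of stripping it
  remap <- character(0)
  lowIns <- which(vtab$low_support & vtab$in_window & vtab$kind == "insertion")
  for (i in lowIns) {
    j <- which(!vtab$low_support & !vtab$biased & !vtab$blacklisted &
                 vtab$in_window & vtab$kind == "insertion" &
                 vtab$position == vtab$position[i] &
                 vtab$length == vtab$length[i])
    if (length(j) == 1) remap[vtab$key[i]] <- vtab$key[j]
  }
  vtab$low_support[vtab$key %in% names(remap)] <- FALSE

  ## primary artifact reason (cross-well recurrence > strand bias > support)
  vtab$reason <- rep(NA_character_, nrow(vtab))
  vtab$reason[vtab$low_support] <- "low_support"
  vtab$reason[vtab$biased] <- "strand_bias"
  vtab$reason[vtab$blacklisted] <- "recurrent_across_wells"
  artifacts <- vtab[!is.na(vtab$reason), , drop = FALSE]

  ## remove filtered variants from signatures (remapping corrected insertion
  ## keys first), then collapse
  badKeys <- vtab$key[vtab$in_window &
                        (vtab$biased | vtab$blacklisted | vtab$low_support)]
  sig <- ex$reads$signature
  if (length(badKeys) || length(remap)) {
    keyOrd <- vtab$key[order(vtab$position, vtab$kind, vtab$length, vtab$alt)]
    sig <- vapply(strsplit(sig, ";"), function(ks) {
      hit <- ks %in% names(remap)
      ks[hit] <- remap[ks[hit]]
      ks <- unique(ks[!(ks %in% badKeys) & ks != "WT"])
      if (length(ks) == 0) "WT" else
        paste(ks[order(match(ks, keyOrd))], collapse = ";")
    }, character(1))
  }
  ori <- ex$reads$orientation
  grp <- tapply(seq_along(sig), sig, identity)
  coll <- data.frame(
    signature = names(grp),
    read_count = vapply(grp, length, 0L),
    plus_count = vapply(grp, function(i) sum(ori[i] == "plus"), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  coll$minus_count <- coll$read_count - coll$plus_count
  coll$fraction <- coll$read_count / coverage
  coll$is_wildtype <- coll$signature == "WT"
  coll$substitution_only <- !coll$is_wildtype &
    vapply(strsplit(coll$signature, ";"),
           function(ks) all(startsWith(ks, "S:")), logical(1))

  ## substitution-only alleles: stricter fraction + strand balance required
  demote <- coll$substitution_only &
    (coll$fraction < subOnlyMinFraction |
       vapply(seq_len(nrow(coll)), function(i)
         strandBiasTest(coll$plus_count[i], coll$minus_count[i],
                        plusFrac, alpha, extremity)$biased, logical(1)))
  if (any(demote)) {
    wt <- which(coll$is_wildtype)
    add <- colSums(coll[demote, c("read_count", "plus_count", "minus_count"),
                        drop = FALSE])
    if (length(wt) == 0) {
      coll <- rbind(coll, data.frame(
        signature = "WT", read_count = 0L, plus_count = 0L, minus_count = 0L,
        fraction = 0, is_wildtype = TRUE, substitution_only = FALSE,
        stringsAsFactors = FALSE))
      wt <- nrow(coll)
    }
    coll$read_count[wt] <- coll$read_count[wt] + add[["read_count"]]
    coll$plus_count[wt] <- coll$plus_count[wt] + add[["plus_count"]]
    coll$minus_count[wt] <- coll$minus_count[wt] + add[["minus_count"]]
    coll <- coll[!demote, , drop = FALSE]
    coll$fraction <- coll$read_count / coverage
  }
  coll <- coll[order(-coll$read_count), , drop = FALSE]
  rownames(coll) <- NULL

  called <- coll[coll$fraction >= minAlleleFraction, , drop = FALSE]
  minor <- coll[coll$fraction >= minorFraction &
                  coll$fraction < minAlleleFraction, , drop = FALSE]
  dropped <- coll[coll$fraction < minorFraction, , drop = FALSE]
  stats$dropped_minor <- sum(minor$read_count) + sum(dropped$read_count)

  list(status = if (nrow(called)) "OK" else "NO_CALL",
       alleles = called,
       minor_allele_evidence = nrow(minor) > 0,
       minor = minor,
       artifacts = artifacts,
       artifact_candidates =
         vtab[, c("key", "kind", "position", "length", "alt", "in_window",
                  "plus", "minus", "p_value", "biased")],
       stats = stats)
}

#' Collapse per-read signatures for one well (two-pass convenience)
#'
#' Thin wrapper over \code{\link{callWellAlleles}} returning just the
#' collapsed allele table; see that function for the filtering rules.
#'
#' @inheritParams callWellAlleles
#' @param ... passed to \code{\link{callWellAlleles}}.
#' @return the \code{alleles} data.frame.
#' @export
buildAlleleTable <- function(alignments, layout, ...) {
  callWellAlleles(alignments, layout, ...)$alleles
}

## ---- report formatting ---------------------------------------------------

#' Format a variant signature for reports
#'
#' Compact cut-site-relative notation, 1-based: \code{del13@-2} is a 13 nt
#' deletion whose left-aligned first deleted base sits 2 bases 5' of the cut
#' site; \code{+1} is the first base 3' of the cut. Insertions carry their
#' sequence (\code{ins2TG@+1}); substitutions their new base
#' (\code{subG@-40}).
#'
#' @param signature a signature string as produced by
#'   \code{\link{extractAlleles}} ("WT" for wildtype).
#' @param cutSite 0-based cut-site offset.
#' @return human-readable allele string.
#' @export
formatSignature <- function(signature, cutSite) {
  if (signature == "WT") return("WT")
  ks <- strsplit(signature, ";")[[1]]
  fmt1 <- function(k) {
    p <- strsplit(k, ":")[[1]]
    pos <- as.integer(p[2])
    rel <- if (pos >= cutSite) paste0("+", pos - cutSite + 1L)
           else as.character(pos - cutSite)
    switch(p[1],
      D = paste0("del", p[3], "@", rel),
      I = paste0("ins", p[3], p[4], "@", rel),
      S = paste0("sub", p[3], "@", rel))
  }
  paste(vapply(ks, fmt1, character(1)), collapse = ";")
}
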