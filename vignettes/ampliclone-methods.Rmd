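---
title: "Genotyping CRISPR-Cas9 edited clones from pooled barcoded amplicons"
author: "ampliclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping CRISPR-Cas9 edited clones from pooled barcoded amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

After transfecting cells with a CRISPR-Cas9 construct and expanding single
clones in a 96-well plate, every well must be genotyped: did non-homologous
end joining leave an indel at the guide site, on one allele or both, and is
the well really clonal? Sanger sequencing of plasmid subclones answers this
slowly and misses clonal heterogeneity; ampliclone instead genotypes a whole
plate from one pooled amplicon sequencing run.

The trick that keeps the assay cheap is combinatorial dual barcoding. Each
well is amplified with a *column-barcoded* forward fusion primer and a
*row-barcoded* reverse fusion primer: 12 + 8 = 20 oligos uniquely index
12 × 8 = 96 wells, because the well identity is the barcode *pair*. The
amplicon is about 200 bp — 100 bp either side of the guide site — so that
single-end reads traverse barcode, primer, cut site and the far barcode, and
a wide range of indel sizes remains detectable.

## Pipeline model

The pipeline runs demultiplex → align → allele calling → genotype → QC.

**Demultiplexing.** Barcode matching is anchored: the leading barcode at the
5′ terminus, the trailing (reverse-complemented) barcode within a small slop
(default 2 nt) of the 3′ terminus. Both orientations are tried, and the
orientation of the match is recorded — for single-end amplicon data this is
the only strand signal available, and it feeds the strand-bias filter. A
read is assigned only when **both** barcodes match within the mismatch
budget (default 1 per barcode) and the minimal-distance candidate is unique;
ties are never broken arbitrarily, because a silently misassigned read
corrupts a genotype. With barcode sets of minimum pairwise distance $d$ and
budget $m \le \lfloor (d-1)/2 \rfloor$, misassignment of an error-free read
is impossible. The packaged example barcodes have $d \ge 5$, so the default
budget of 1 leaves no ambiguity even after one sequencing error; the
barcode-set validator defaults to requiring $d \ge 3$, the minimum for
1-mismatch tolerance.

**Alignment.** Trimmed reads are aligned to the reference amplicon with an
affine-gap *glocal* model: the read must align end to end (after trimming it
is wholly amplicon-derived), reference overhangs are free. A gap of length
$L$ costs $g_{open} + L \cdot g_{ext}$ with defaults match +2, mismatch 4,
$g_{open}=5$, $g_{ext}=1$. The cheap extension is deliberate: a 40 nt
cut-site deletion costs 45 rather than being shredded into mismatches and
short gaps, which is the single most important alignment property for CRISPR
genotyping. The dynamic program is exact (no banding); tie-breaking in the
traceback is deterministic, and indels are then left-aligned — shifted
maximally 5′-ward within homopolymers and repeats — so that every read
carrying the same physical indel produces the same CIGAR. Alignments scoring
below $0.4 \times \mathrm{match} \times |read|$ are declared unalignable.

**Allele signatures.** Each aligned read collapses to its *allele
signature*: the ordered, left-aligned variants that touch the cut-site
window (cut ± 25 nt by default; a deletion counts if its reference interval
overlaps the window, so long deletions that start upstream still count). An
empty signature is the wildtype allele. Variants outside the window are
never allele-defining; they are candidate sequencing artifacts.

**Artifact filtering.** Three mechanisms, mirroring what an experienced eye
does in a genome browser:

1. *Strand bias.* True alleles appear in roughly equal proportion on both
   read orientations; platform artifacts sit almost entirely on one. Each
   variant's plus-read fraction is tested against the well's overall plus
   fraction with an exact two-sided binomial test (α = 0.01, uncorrected)
   **and** must be extreme (≥ 0.9 or ≤ 0.1) to be called biased — the
   extremity guard carries most of the specificity, and small supports can
   never trip it.
2. *Cross-well recurrence.* Artifacts recur at the same reference position
   in many wells. Out-of-window, strand-biased variants seen at the same
   (position, kind) in ≥ 3 wells are blacklisted plate-wide; in-window
   variants supported on both strands can never enter the blacklist. The
   default of 3 wells avoids blacklisting a true allele shared by duplicate
   clones.
3. *Low support.* A real allele component rides at the allele fraction
   (≥ 0.20 by default); stray per-read sequencing errors sit near the
   per-base error rate. In-window variants supported by fewer than 5% of the
   well's reads are stripped from signatures before collapsing, which
   returns error-carrying reads to their parent allele. Without this step,
   at a 1% per-base error rate roughly 40% of reads would carry some stray
   in-window error and allele fractions would be systematically diluted.
   One refinement: an error *inside* an inserted sequence changes the
   insertion's bases but not its placement or length, so a low-support
   insertion co-located with a major same-length insertion is remapped onto
   it rather than stripped.

**Calling and classification.** Signatures collapse by identity; a well
needs ≥ 100 aligned reads to be called (below that it is NO_CALL). Alleles
at fraction ≥ 0.20 are called; fractions in [0.05, 0.20) do not change the
genotype but set a minor-evidence flag — the practical remedy for such wells
is re-cloning by serial dilution, so the flag is surfaced rather than
escalated. Substitution-only alleles face a stricter bar (fraction ≥ 0.25
plus strand balance) because single-base errors dominate the platform noise.
The called multiset maps onto five classes: wildtype; heterozygous (wildtype
+ one mutant); homozygous (one mutant, no wildtype); compound heterozygous
(two distinct mutants); mixed (more than two called alleles — wildtype
counts as an allele here, since a true diploid clone cannot carry three).
Frameshift status is the net indel length modulo 3. The cohort summary
reports the biallelic-disruption count (homozygous + compound heterozygous)
and the mutated count under both conventions — counting uncallable wells as
insulted (total − wildtype) and restricting to callable wells — because the
choice changes the headline rate and both are defensible.

**Coverage QC.** Pooling PCR products without per-well normalization is
justified when depth is reasonably even. The uniformity rule flags wells
outside [mean/5, 5 × mean] (closed interval), with the mean over wells that
received any reads; empty wells reflect failed clones, not pooling skew, and
are listed separately. The rule is scale invariant.

## What the simulator emulates

`simulateRun()` builds reads exactly as the library is built on the bench:
column barcode + forward primer + allele-modified amplicon core + reverse
complement of reverse primer + reverse complement of row barcode, emitted in
either orientation with probability 1/2. On top it layers:

- lognormal per-well depth (default mean 2455×, σ = 0.7, spanning roughly
  300–6600×, the depth profile of a pooled plate without normalization);
- uniform per-base substitution errors (default 1%), with a separate rate
  for barcode regions;
- homopolymer ±1 indels — for a run of length $L \ge 3$, an indel with
  probability $\min(rate \cdot (L-2), 0.1)$ — a minimal model of the
  dominant Ion-Torrent-style error mode;
- strand-restricted recurrent artifacts: substitutions or 1 nt indels
  applied only to reads of one orientation at a fixed reference position in
  a configurable set of wells, giving the strand-bias and recurrence filters
  falsifiable targets.

`makeScreenCohort()` composes a 67-well screen with a fixed class
composition — 10 homozygous, 27 compound heterozygous, 4 heterozygous, 2
wildtype, 21 mixed, and 3 wells forced to sub-threshold depth (30 reads) so
they cannot be called — with random 1–30 nt indel alleles overlapping the
cut site and two injected plate-wide artifacts. Mixed wells carry three
distinct alleles at ~1/3 each, the composition a two-founder-cell well
produces; at the default 0.20 call threshold this is also robustly
recoverable at moderate depth, whereas four alleles at 0.25 would sit on the
threshold itself. The cohort's mean depth defaults to 1000×, a deliberately
modest figure that keeps a full end-to-end run on one CPU in minutes while
staying far above the 100-read call gate.

What the simulator does **not** model: flow-space signal artifacts and
context-dependent error spectra, quality-score variation (all bases are
emitted at phred 40), chimeric PCR products, index hopping, and primer-site
polymorphisms. Passing the recovery suites therefore demonstrates that the
algorithmic chain is lossless under the modelled error phenomenology, not
that every real run will be called perfectly — in particular, real barcode
sets should be screened with `validateBarcodeSet()` and real artifacts may
be less cleanly strand-restricted than the simulated ones.

## Numerical and design choices

- Coordinates are 0-based half-open internally; every user-facing report is
  1-based, and allele notation is cut-site-relative (`del13@-2` starts 2 nt
  5′ of the cut).
- The plate is fixed at rows A–H × columns 1–12 (forward = column,
  reverse = row); smaller plates are allowed, larger rejected.
- Barcode lengths may differ within a set; matching uses each barcode's own
  length.
- Alignment tie-breaks prefer diagonal continuation, then gap extension over
  gap opening, then the smallest reference end offset; left-alignment then
  canonicalizes indel placement regardless of traceback details.
- The aligner's unalignable floor (0.4 × match × read length) is permissive
  on purpose: a read with a 50 nt deletion out of 160 nt still scores well
  above it, while unrelated sequence falls far below.
- The binomial strand test is a screen, not an inference; its α is
  uncorrected and the extremity guard (≥ 0.9 / ≤ 0.1) does the heavy
  lifting. All thresholds are explicit arguments and recorded in the run
  manifest.
- Degenerate inputs: an empty read set produces empty reports; an all-empty
  plate is a QC error; wells losing every allele to filtering are NO_CALL;
  reads shorter than the minimum length or matching only one barcode are
  tallied by reason rather than dropped silently.

## Problem sizes used in the validation suites

The bundled suites exercise: the full 96-well plate at ~10,000 reads for
demultiplexing fidelity (≥ 95% assignment, zero cross-well misassignments at
1% substitution error); 500 randomized read/reference pairs against an
independent brute-force affine-gap oracle; a 20-well screen with five
injected strand-restricted artifacts for filter operating characteristics;
and the 67-well cohort at mean depth 1000× for class-exact end-to-end
recovery. These sizes are the package's validation conditions and are
reproduced by `scripts/acceptance.R`.

## Known limitations

- Alignment is to the amplicon only; reads from off-target loci are merely
  "unalignable", not mapped genome-wide.
- Diploid genotype classes only; higher ploidy surfaces as MIXED with the
  raw allele count reported.
- No base-quality awareness anywhere in scoring or filtering.
- Single plate, single pooled FASTQ per run; no multi-run merging.
- Exact (unbanded) alignment costs O(|read| × |reference|) per read — fine
  for 200 bp amplicons, not meant for long references.
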