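# ampliclone

Genotyping of CRISPR-Cas9 edited cell clones from one pooled, dual-barcoded
amplicon sequencing run.

## The problem

After CRISPR-Cas9 transfection, single-cell clones expanded in a 96-well
plate must be screened: which wells carry indels at the guide site, on one
allele or both — and which wells are not clonal at all? Screening clone by
clone (plasmid subcloning + Sanger) is slow, expensive, and blind to clonal
heterogeneity.

ampliclone implements the pooled alternative. Each well is amplified with a
**column-barcoded forward** primer and a **row-barcoded reverse** primer: the
well identity is the barcode *pair*, so 12 + 8 = 20 oligos uniquely index
12 × 8 = 96 wells. The ~200 bp amplicon spans the guide site with ~100 bp
flanks, all products are pooled (no per-well normalization) and sequenced
single-ended; the package does the rest in software:

1. **demux** — anchored dual-barcode matching in either read orientation
   (the orientation doubles as the strand signal), ambiguous reads never
   assigned;
2. **align** — exact affine-gap *glocal* alignment to the amplicon
   (match +2, mismatch 4, gap open 5, gap extend 1), the cheap extension
   keeping a 10–50 nt cut-site deletion as one gap; indels left-aligned into
   canonical form;
3. **call** — per-read allele signatures in the cut-site window (±25 nt)
   collapsed into well alleles, with sequencing artifacts removed by an
   exact binomial **strand-bias test** (true alleles sit on both strands,
   artifacts on one), a **cross-well recurrence blacklist** (artifacts recur
   at the same position in many wells), and a low-support floor;
4. **genotype** — each well classified as WILDTYPE, HETEROZYGOUS,
   HOMOZYGOUS, COMPOUND_HETEROZYGOUS or MIXED (>2 alleles — a non-clonal
   well), with frameshift annotation (net indel length mod 3) and a cohort
   summary including the biallelic-disruption count;
5. **qc** — the coverage-uniformity rule: wells outside [mean/5, 5×mean]
   are flagged.

A full simulator (`simulateRun()`, `makeScreenCohort()`) generates whole
screening runs with per-read ground truth — allele mixtures, lognormal
depth, substitution and homopolymer-indel errors, barcode errors, and
strand-restricted recurrent artifacts — so every stage is testable without
instrument data.

## Worked example

Simulate one compound-heterozygous clone in well A6 — a 1 bp deletion on one
allele and a 13 bp deletion on the other — and genotype it:

```r
library(ampliclone)

layout <- exampleLayout()        # 12 x 8 plate, 200 bp amplicon, cut at 101
cfg <- simConfig(layout, list(A6 = list(
  alleles   = list(alleleDeletion(1, 0), alleleDeletion(13, -6)),
  fractions = c(0.5, 0.5), depth = 400L)))
sim <- simulateRun(cfg, seed = 7)

dm  <- demultiplex(sim$reads, layout)
dm
#> DemuxResult: 400 reads, 398 assigned ( 99.5 % ) across 1 wells

a   <- dm$assignments[dm$assignments$well == "A6", ]
aln <- alignReads(setNames(a$trimmed, a$read_id), referenceAmplicon(layout))
aln$orientation <- a$orientation
cw  <- callWellAlleles(aln, layout)
cw$alleles[, c("signature", "read_count", "plus_count", "minus_count", "fraction")]
#>   signature read_count plus_count minus_count  fraction
#> 1   D:100:1        193        105          88 0.4849246
#> 2   D:93:13        179         89          90 0.4497487

classifyGenotype(cw$alleles)
#> [1] "COMPOUND_HETEROZYGOUS"
sapply(cw$alleles$signature, formatSignature, cutSite = cutSite(layout))
#>     D:100:1     D:93:13
#>   "del1@+1"  "del13@-7"
```

Both alleles are recovered at ~50% on balanced strands: a 1 nt deletion at
the first base 3′ of the cut and a 13 nt deletion whose left-aligned start
is 7 nt 5′ of it. `runPipeline(sim$reads, layout)` wraps the same chain and
adds the genotype report, cohort summary, QC and TSV/SAM outputs;
`makeScreenCohort()` builds a full 67-clone screen (10 homozygous, 27
compound het, 4 het, 2 wildtype, 21 mixed, 3 too shallow to call — 37
clones with both alleles disrupted).

A command-line front end covering
`design / demux / genotype / qc / simulate / run` ships in
`inst/cli/ampliclone`.

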