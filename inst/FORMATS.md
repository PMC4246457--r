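# File formats

All report positions are 1-based; allele notation is cut-site-relative
(`del13@-2` = 13 nt deletion whose left-aligned first deleted base lies 2 nt
5' of the cut site; `+1` is the first base 3' of the cut). Every report
directory contains a `<run>_manifest.tsv` listing the tool version and the
effective value of every threshold that produced the reports.

## Layout config (YAML, read by `readPlateLayout()`)

```yaml
column_barcodes:        # id: sequence, plate columns 1..12 in order
  C01: AAATTACCCG
row_barcodes:           # id: sequence, plate rows A..H in order
  R01: TTGCGTTTAA
fwd_primer: CGGCGGAGAGGAGACTATCA
rev_primer: TATCACTTATGTATGCGTAG
reference_amplicon: CGGCGG...   # or: reference_fasta: amplicon.fasta
cut_site: 101           # 1-based position in the amplicon
flank: 100              # design record: nt either side of the guide
```

## Demultiplexing outputs (`writeDemuxFastq()`)

- `<run>_<well>.fastq` — trimmed (barcodes + primers removed), plus-oriented
  reads per well; `<run>_unassigned.fastq` — original unassigned reads.
- `<run>_demux_summary.tsv` — columns `well`, `reads`, `fraction`
  (fraction of all input reads), one row per layout well plus `unassigned`.

## Genotype report (`<run>_genotypes.tsv`)

One row per occupied well: `well`, `class` (WILDTYPE / HETEROZYGOUS /
HOMOZYGOUS / COMPOUND_HETEROZYGOUS / MIXED / NO_CALL), `coverage` (aligned
reads), `n_alleles`, `alleles` (cut-relative notation, " / "-separated),
`fractions`, `frameshift` (per allele: frameshift / in-frame / n/a),
`minor_allele_evidence` (TRUE when sub-threshold alleles at 5-20% were
seen — consider re-cloning), `plus_fraction` (well strand balance).

## Allele table (`<run>_alleles.tsv`)

One row per called allele: `well`, `rank` (by read support), `allele`,
`read_count`, `plus`, `minus`, `fraction`.

## Cohort summary (`<run>_cohort_summary.tsv`)

`metric`/`value` rows: the six class counts, `total`, `callable`
(total minus NO_CALL), `biallelic_disrupted` (homozygous + compound het),
`mutated_including_nocall` (total - wildtype) and
`mutated_excluding_nocall` (callable - wildtype).

## QC report (`<run>_qc.tsv`)

`well`, `depth`, `flagged` (outside [mean/5, 5*mean]), `empty`.

## SAM output (`--sam-out` / `writeSam()`)

One SAM per well against the single `amplicon` reference (FASTA written
alongside). CIGAR uses M/I/D only; reads demultiplexed from the minus
orientation carry FLAG 16 with SEQ stored in reference orientation. Loads
directly in IGV.

## Simulator truth TSV (`simulateRun(..., truthPath=)`)

`read_id`, `well`, `orientation` (plus/minus emission), `allele_label`
(e.g. `WT`, `del13@-6`, cut-relative 0-based spec offsets).
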