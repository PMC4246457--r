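column_barcodes:
  C01: AAATTACCCG
  C02: AGAACTCCGC
  C03: GGTGTAGCTG
  C04: GATGTCCTGA
  C05: AACCTAAGAG
  C06: CTGCTTATCG
  C07: TCCGTTCTTC
  C08: CGGAGAAGCG
  C09: ATTGGGCGAT
  C10: AGGGTCTAAG
  C11: CGTTTGATCT
  C12: GACAGTCGTC
row_barcodes:
  R01: TTGCGTTTAA
  R02: GAAACCATTT
  R03: TTGTTGACTT
  R04: ACGAGGTACT
  R05: AGCATCTTGA
  R06: CACCGGTTGA
  R07: TGACTGGTAC
  R08: CGCCCGACGT
fwd_primer: CGGCGGAGAGGAGACTATCA
rev_primer: TATCACTTATGTATGCGTAG
reference_amplicon: CGGCGGAGAGGAGACTATCATATGACCAGCACTGCCGATCTTCGTCGGTGCCTCACTAAAAGCAGTTCAGTTGGAGTAGAATACCTTGATAGGCATTTTTGGTGCCCATGCCCTTGTCCCTATGCCTACCATAGTGTGGAGCTCTTCGCAATTCGTGCGGGGGGTTGTAACGTAATTTGACTACGCATACATAAGTGATA
cut_site: 101
flank: 100
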