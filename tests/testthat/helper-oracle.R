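## Independent score-only affine-gap glocal DP, written against the scoring
## definition rather than the package aligner: row-vectorized recurrences,
## with the within-row deletion recursion collapsed to a running maximum.
## Used as the oracle for alignment scores.
oracleScore <- function(read, ref, match = 2, mismatch = 4,
                        gapOpen = 5, gapExtend = 1) {
  r <- strsplit(read, "")[[1]]
  f <- strsplit(ref, "")[[1]]
  m <- length(r); n <- length(f)
  NEGI <- -1e9
  Mp <- rep(0, n + 1)        # row 0: free reference prefix
  Ip <- rep(NEGI, n + 1)
  Dp <- rep(NEGI, n + 1)
  for (i in seq_len(m)) {
    s <- ifelse(r[i] == f, match, -mismatch)
    prevBest <- pmax(Mp, Ip, Dp)
    Mc <- c(NEGI, prevBest[seq_len(n)] + s)
    Ic <- pmax(Ip - gapExtend, pmax(Mp, Dp) - gapOpen - gapExtend)
    ## D[j] = max_{k<j} ( max(M[k], I[k]) - gapOpen - (j-k)*gapExtend )
    A <- pmax(Mc, Ic) + gapExtend * (0:n) - gapOpen
    Dc <- c(NEGI, cummax(A[seq_len(n)])) - gapExtend * (0:n)
    Mp <- Mc; Ip <- Ic; Dp <- Dc
  }
  max(pmax(Mp, Ip, Dp))
}

randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

## error-free library molecule for a given well, in plus orientation
makeCleanRead <- function(layout, colIdx, rowIdx,
                          core = referenceAmplicon(layout)) {
  paste0(columnBarcodes(layout)[[colIdx]], core,
         revComp(rowBarcodes(layout)[[rowIdx]]))
}

## apply k substitutions at given 1-based positions (cycling through bases)
mutateAt <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

tinyLayout <- function(columns = 3, rows = 2) exampleLayout(columns, rows)
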