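# Shared fixtures and independent oracles, all built in code.

# Write named aligned sequences to a temp FASTA and read them back as a
# QueryAlignment (exercises the I/O path on every construction).
toyAlignment <- function(seqs, query = names(seqs)[1], ext = ".fasta",
                         format = "auto") {
  f <- tempfile(fileext = ext)
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), f)
  readAlignment(f, format = format, query = query)
}

# Brute-force McBASC oracle: explicit double loop over sequence pairs.
oracleCovariation <- function(m, i, j, minSeqPairs = 10) {
  n <- nrow(m)
  si <- numeric(0); sj <- numeric(0)
  M <- mclachlanMatrix()
  for (k in seq_len(n - 1)) {
    for (l in seq(k + 1, n)) {
      r <- c(m[k, i], m[l, i], m[k, j], m[l, j])
      if (all(r != "-")) {
        si <- c(si, M[r[1], r[2]])
        sj <- c(sj, M[r[3], r[4]])
      }
    }
  }
  if (length(si) < minSeqPairs) return(0)
  if (sd(si) == 0 || sd(sj) == 0) return(0)
  cor(si, sj)
}

# Brute-force AUC oracle: concordant positive-negative pairs, ties = 1/2.
oracleAuc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Log-multinomial entropy S = ln(N! / prod n!) via log-gamma.
logFactorialEntropy <- function(counts) {
  lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
}

# Random uniform-background alignment (no planted structure).
randomAlignment <- function(L, N, seed, gapRate = 0) {
  generateCoupledMsa(L = L, N = N, gapRate = gapRate, seed = seed)$alignment
}

# Build a PairCountTable-bearing two-column alignment from explicit residue
# pairs; the first pair is the query row.
pairColumnAlignment <- function(pairs) {
  seqs <- vapply(pairs, paste0, character(1), collapse = "")
  names(seqs) <- c("query", paste0("s", seq_along(pairs)[-1]))
  toyAlignment(seqs)
}
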