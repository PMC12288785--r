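# independent transliteration of the doubly trimmed weighted-mean TMM,
# used as the literal-formula oracle in the normalisation tests
tmm_oracle <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  lib <- colSums(counts)
  cpm <- t(t(counts) / lib) * 1e6
  q75 <- apply(cpm, 2, quantile, 0.75)
  ref <- which.min(abs(q75 - mean(q75)))
  f <- sapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    y <- counts[, s]; r <- counts[, ref]
    ok <- y > 0 & r > 0
    y <- y[ok]; r <- r[ok]
    M <- log2((y / lib[s]) / (r / lib[ref]))
    A <- 0.5 * log2((y / lib[s]) * (r / lib[ref]))
    if (max(A) - min(A) < 1e-10 || max(M) - min(M) < 1e-10) return(1)
    n <- length(M)
    keep <- rank(M, ties.method = "first") >= floor(n * trim_M) + 1 &
      rank(M, ties.method = "first") <= n - floor(n * trim_M) &
      rank(A, ties.method = "first") >= floor(n * trim_A) + 1 &
      rank(A, ties.method = "first") <= n - floor(n * trim_A)
    w <- 1 / ((lib[s] - y) / (lib[s] * y) + (lib[ref] - r) / (lib[ref] * r))
    2^(sum((w * M)[keep]) / sum(w[keep]))
  })
  f / exp(mean(log(f)))
}
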