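# Independent oracles used by the tests. These deliberately avoid the code
# paths (and the alignment engine) used by the package itself.

# Brute-force Smith-Waterman local alignment, linear gap penalty.
# Scoring: match +1, mismatch -1, gap -2. Returns the best score only.
sw_oracle_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  n <- length(a); m <- length(b)
  prev <- numeric(m + 1)
  best <- 0
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      cur[j + 1] <- max(0, prev[j] + sub[j], prev[j + 1] + gap, cur[j] + gap)
    }
    best <- max(best, max(cur))
    prev <- cur
  }
  best
}

# One-way fixed-effects ANOVA F statistic from explicit sums of squares.
anova_f_oracle <- function(y, g) {
  g <- as.factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(g) - 1
  dfw <- length(y) - nlevels(g)
  (ssb / dfb) / (ssw / dfw)
}

# Pooled-variance two-sample t statistic (classical formula).
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}
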