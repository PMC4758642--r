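## Independent oracles used by the tests. These re-derive expected values
## from first principles and must stay independent of the package internals.

## Otsu threshold by exhaustive search over all 256 candidate histogram
## levels, maximizing the between-class variance.
otsuOracle <- function(x, levels = 256L) {
  mn <- min(x); mx <- max(x)
  xs <- (as.vector(x) - mn) / (mx - mn)
  breaks <- seq(0, 1, length.out = levels + 1L)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  counts <- hist(xs, breaks = breaks, plot = FALSE)$counts
  n <- sum(counts)
  vars <- rep(NA_real_, levels)
  for (k in seq_len(levels)) {
    w1 <- sum(counts[1:k])
    w2 <- n - w1
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(counts[1:k] * mids[1:k]) / w1
    m2 <- sum(counts[(k + 1):levels] * mids[(k + 1):levels]) / w2
    vars[k] <- w1 * w2 * (m1 - m2)^2
  }
  best <- max(vars, na.rm = TRUE)
  ## empty bins yield exactly identical variance to the previous bin; ties
  ## resolve to the midpoint of the first and last maximizing bins
  bestK <- which(vars == best)
  t01 <- (mids[bestK[1]] + mids[bestK[length(bestK)]]) / 2
  mn + t01 * (mx - mn)
}

## Optimal global alignment score by exhaustive enumeration of all
## alignments (no dynamic programming): moves are diagonal (substitute),
## delete (residue of a vs gap) and insert (gap vs residue of b); a gap run
## of length L costs open + L * extend.
nwEnumScore <- function(a, b, S, open, extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  rec <- function(i, j, prev) {
    if (i == la && j == lb) return(0)
    best <- -Inf
    if (i < la && j < lb)
      best <- max(best, S[av[i + 1], bv[j + 1]] + rec(i + 1, j + 1, "M"))
    if (i < la)
      best <- max(best,
                  -(extend + if (prev != "D") open else 0) +
                    rec(i + 1, j, "D"))
    if (j < lb)
      best <- max(best,
                  -(extend + if (prev != "I") open else 0) +
                    rec(i, j + 1, "I"))
    best
  }
  rec(0L, 0L, "M")
}

## uniform random peptide
randomPeptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
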