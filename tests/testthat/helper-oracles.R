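# Independent brute-force oracles: direct-enumeration implementations of
# each statistic, kept deliberately naive and separate from the package's
# code paths.

oracle_normfinder <- function(x) {
  grand <- mean(x)
  scores <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    res <- numeric(ncol(x))
    for (s in seq_len(ncol(x))) {
      res[s] <- x[g, s] - mean(x[g, ]) - mean(x[, s]) + grand
    }
    scores[g] <- sd(res)
  }
  setNames(scores, rownames(x))
}

oracle_pairwise_sd_score <- function(x) {
  # geNorm M on the full panel == comparative delta-Ct score.
  scores <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    disp <- c()
    for (h in seq_len(nrow(x))) {
      if (h == g) next
      disp <- c(disp, sd(x[g, ] - x[h, ]))
    }
    scores[g] <- mean(disp)
  }
  setNames(scores, rownames(x))
}

oracle_bestkeeper_sd <- function(x) {
  setNames(apply(x, 1L, sd), rownames(x))
}

# Exhaustive recursion over all global-alignment decompositions.
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      best <- max(best, rec(i - 1L, j - 1L) +
                    (if (av[i] == bv[j]) match else mismatch))
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(av), length(bv))
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1L):1L) adj[i] <- min(adj[i], adj[i + 1L])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
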