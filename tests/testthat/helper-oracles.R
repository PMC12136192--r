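# Independent brute-force oracles. These deliberately use naive loops and
# set operations so they share no code path with the package implementation.

# Direct-count quantile profile: ranking is a character vector of marker ids,
# strongest association first.
oracle_positive_profile <- function(module_markers, ranking, cutpoints) {
  M <- length(ranking)
  m <- length(module_markers)
  O <- integer(length(cutpoints))
  E <- numeric(length(cutpoints))
  for (i in seq_along(cutpoints)) {
    k <- floor((1 - cutpoints[i]) * M + 1e-9)  # guard against 9.999... artifacts
    top <- if (k >= 1) ranking[1:k] else character()
    O[i] <- sum(module_markers %in% top)
    E[i] <- m * k / M
  }
  list(observed = O, expected = E)
}

oracle_chi <- function(O, E, kappa) {
  s <- 0
  for (i in seq_along(O)) s <- s + (O[i] - E[i]) / sqrt(E[i] + kappa)
  s
}

# Exhaustive greedy clumping: repeatedly claim the best-p marker and discard
# its supra-threshold partners.
oracle_clump <- function(assoc, ld, r2_threshold) {
  linked <- ld[ld$R2 > r2_threshold, , drop = FALSE]
  order_ids <- assoc$MARKER[order(assoc$PVALUE, assoc$MARKER)]
  claimed <- character()
  retained <- character()
  for (m in order_ids) {
    if (m %in% claimed) next
    retained <- c(retained, m)
    claimed <- c(claimed, m)
    nb <- c(linked$MARKER_B[linked$MARKER_A == m],
            linked$MARKER_A[linked$MARKER_B == m])
    claimed <- union(claimed, nb)
  }
  assoc$MARKER[assoc$MARKER %in% retained]
}

# Step-up BH from the defining formula q_(i) = min_{j>=i} p_(j) * m / j, capped.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail by full enumeration of the support.
oracle_hyper_tail <- function(overlap, K, N, n) {
  hi <- min(n, K)
  if (overlap > hi) return(0)
  j <- overlap:hi
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
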