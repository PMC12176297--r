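# Independent brute-force oracles used across the suite.

# Exhaustive O(L^2) Otsu: scan every cut point, recompute class weights and
# means from scratch each time.
otsu_bruteforce <- function(levels, counts) {
  o <- order(levels)
  levels <- levels[o]
  counts <- counts[o]
  n <- sum(counts)
  best <- -Inf
  best_t <- levels[1]
  for (k in seq_len(length(levels) - 1L)) {
    i0 <- seq_len(k)
    i1 <- seq.int(k + 1L, length(levels))
    w0 <- sum(counts[i0]) / n
    w1 <- sum(counts[i1]) / n
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[i0] * levels[i0]) / sum(counts[i0])
    m1 <- sum(counts[i1] * levels[i1]) / sum(counts[i1])
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best + 1e-12) {
      best <- v
      best_t <- levels[k]
    }
  }
  best_t
}

# Two-sided conditional exact p for a 2x2 table by direct hypergeometric
# tail summation (sum of all table probabilities not exceeding the
# observed one).
exact_p_bruteforce <- function(a, b, c, d) {
  m <- a + b        # first margin
  n <- c + d
  k <- a + c        # second margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Single-linkage cluster count at a distance cutoff via hclust (independent
# of the union-find implementation in the package).
single_linkage_count <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n <= 1L) return(n)
  hc <- hclust(dist(coords), method = "single")
  length(unique(cutree(hc, h = cutoff)))
}

# Tiny deterministic grouped data for statistics tests.
make_grouped <- function(seed = 1) {
  set.seed(seed)
  data.frame(
    value = c(rnorm(20, 10, 2), rnorm(25, 12, 2), rnorm(22, 9, 2)),
    genotype = rep(c("wt", "mutA", "mutB"), c(20, 25, 22)),
    replicate = unlist(lapply(c(20, 25, 22), function(n)
      rep(c("r1", "r2"), length.out = n))))
}
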