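# Independent oracles used across tests. Deliberately written from first
# principles (or delegated to an unrelated package), not via ploidpop
# internals.

# Brute-force split check: S (given as tip labels) is a split of unrooted
# `tree` iff S is monophyletic after rooting at a tip outside S.
oracle_is_split <- function(tree, side) {
  out <- setdiff(tree$tip.label, side)
  if (length(side) < 2L || length(out) < 2L) return(FALSE)
  rooted <- ape::root(tree, outgroup = out[1L], resolve.root = TRUE)
  ape::is.monophyletic(rooted, side)
}

# RF by exhaustive subset enumeration (fine for <= 8 leaves).
oracle_rf <- function(t1, t2) {
  labs <- sort(t1$tip.label)
  n <- length(labs)
  ref <- labs[1L]
  others <- labs[-1L]
  count <- 0L
  for (sz in 2:(n - 2L)) {
    combs <- utils::combn(others, sz, simplify = FALSE)
    for (side in combs) {          # sides not containing the reference tip
      in1 <- oracle_is_split(t1, side)
      in2 <- oracle_is_split(t2, side)
      if (xor(in1, in2)) count <- count + 1L
    }
  }
  count
}

# Naive per-site double-loop mean pairwise difference (total, per locus).
oracle_pi_total <- function(seqs) {
  n <- nrow(seqs)
  tot <- 0
  np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- 0
    for (s in seq_len(ncol(seqs))) if (seqs[i, s] != seqs[j, s]) d <- d + 1
    tot <- tot + d
    np <- np + 1
  }
  tot / np
}

# Tajima's D written out directly from the 1989 definitions.
oracle_tajima_d <- function(pi_total, S, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Hudson Fst by explicit loops.
oracle_fst <- function(seqs, idxA, idxB) {
  pd <- function(i, j) sum(seqs[i, ] != seqs[j, ])
  mean_within <- function(idx) {
    v <- c()
    for (i in 1:(length(idx) - 1)) for (j in (i + 1):length(idx))
      v <- c(v, pd(idx[i], idx[j]))
    mean(v)
  }
  hw <- (mean_within(idxA) + mean_within(idxB)) / 2
  v <- c()
  for (i in idxA) for (j in idxB) v <- c(v, pd(i, j))
  hb <- mean(v)
  1 - hw / hb
}

# Exact two-sided rank-sum p-value by enumeration of all group assignments.
oracle_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  w_obs <- sum(rank(pooled)[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na, simplify = FALSE)
  ws <- vapply(combs, function(idx)
    sum(rank(pooled)[idx]) - na * (na + 1) / 2, 0)
  p <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  p
}

# Pearson r and two-sided t-test p from the closed forms.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Minimal base_freq_set builder for hand-made frequency multisets.
make_freq_set <- function(freqs, individual = "x") {
  out <- data.frame(individual = individual, locus = "L1",
                    site = seq_along(freqs) - 1L, freq = freqs,
                    depth = 50L, signal_posterior = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("base_freq_set", "data.frame")
  out
}
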