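# Independent oracles and small fixture builders used across the suite.

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins, probability of each from explicit log-factorials (independent of
# dhyper), sum those no more probable than the observed table.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  N <- r1 + r2
  lp_table <- function(x) {
    # P(table with top-left x | margins), via factorials
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(c2 + 1) -
      lgamma(N + 1) - lgamma(x + 1) - lgamma(r1 - x + 1) -
      lgamma(c1 - x + 1) - lgamma(N - r1 - c1 + x + 1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  lp <- vapply(support, lp_table, numeric(1))
  p <- exp(lp)
  p_obs <- exp(lp_table(a))
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Full-permutation two-sided Mann-Whitney p by enumerating every split of the
# pooled sample (combn), for small n.
mw_permutation_oracle <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs_u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(length(pooled), m)
  us <- apply(splits, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mn <- m * length(y)
  mean(abs(us - mn / 2) >= abs(obs_u - mn / 2) - 1e-9)
}

# A one-chromosome genome for focused tests.
single_chrom_genome <- function(len = 1e6, cen = 4e5, name = "chrT") {
  tibble::tibble(chrom = name, length = as.integer(len), cen = as.integer(cen))
}

# Evenly spaced markers on one chromosome.
even_markers <- function(n = 100, len = 1e6, name = "chrT", from = 1000) {
  pos <- as.integer(round(seq(from, len - 1000, length.out = n)))
  tibble::tibble(chrom = name, pos = pos, id = sprintf("t%04d", seq_len(n)))
}

# Build segments directly from a per-marker state vector (bypassing the
# caller), for classification tests with hand-laid patterns.
segments_from_states <- function(markers, states, min_markers = 1) {
  calls <- dplyr::mutate(markers, state = states)
  segment_genome(calls, min_markers = min_markers)
}
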