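# Independent brute-force oracles used to cross-check the fast paths.

# O(n*m) all-pairs overlap count: number of a-intervals overlapping >= 1
# b-interval, by explicit pairwise comparison.
brute_force_overlap_count <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  hits <- vapply(seq_len(nrow(a)), function(i) {
    any(a$chrom[i] == b$chrom &
          pmax(a$start[i], b$start) < pmin(a$end[i], b$end))
  }, logical(1))
  sum(hits)
}

# Poisson upper tail by direct pmf summation at high precision:
# P(X >= k) = sum_{j >= k} pmf(j), terms added until negligible.
poisson_sf_oracle <- function(count, lam) {
  j <- count
  total <- 0
  repeat {
    term <- exp(j * log(lam) - lam - lgamma(j + 1))
    total <- total + term
    j <- j + 1
    if ((term < total * 1e-18 && j > lam) || j > count + 10000) break
  }
  total
}

# One-sided exact test for a 2x2 table by full enumeration of tables with
# the observed margins: P(methylated count on group A >= observed).
hypergeom_tail_oracle <- function(xa, na, xb, nb) {
  k <- xa + xb                    # total methylated (margin)
  lo <- max(0L, k - nb)
  hi <- min(na, k)
  probs <- vapply(lo:hi, function(x) {
    choose(na, x) * choose(nb, k - x) / choose(na + nb, k)
  }, numeric(1))
  sum(probs[(lo:hi) >= xa])
}

# Random small interval set on a toy chromosome.
random_interval_set <- function(n, chrom_len = 1e5, chroms = "chr1") {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(chrom_len - 100, n, replace = TRUE) - 1
  len <- sample.int(500, n, replace = TRUE)
  gintervals(chrom, start, pmin(start + len, chrom_len))
}
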