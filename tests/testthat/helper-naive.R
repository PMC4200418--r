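# Independent naive MIC enumerator used as an oracle against the package's
# bitmask-based exhaustive engine. Deliberately shares no code with the
# package: recursive subset generation instead of mask arithmetic, mutual
# information via entropy sums instead of the p*log(p/q) form, its own
# budget rule.

naive_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

naive_mi <- function(counts) {
  n <- sum(counts)
  naive_entropy(rowSums(counts) / n) + naive_entropy(colSums(counts) / n) -
    naive_entropy(as.vector(counts) / n)
}

# all non-empty subsets of 1..m, by recursion on the first element
naive_subsets <- function(m) {
  recurse <- function(from) {
    if (from > m) return(list(integer(0)))
    rest <- recurse(from + 1L)
    c(rest, lapply(rest, function(s) c(from, s)))
  }
  Filter(length, recurse(1L))
}

naive_bins <- function(ranks, cuts) {
  vapply(ranks, function(r) 1L + sum(cuts < r), integer(1))
}

naive_mic <- function(xs, ys, alpha = 0.6) {
  n <- length(xs)
  xr <- rank(xs, ties.method = "first")
  yr <- rank(ys, ties.method = "first")
  budget <- max(floor(n^alpha), 4)
  best <- -Inf
  for (xc in naive_subsets(n - 1L)) {
    nx <- length(xc) + 1L
    if (nx * 2 > budget) next
    for (yc in naive_subsets(n - 1L)) {
      ny <- length(yc) + 1L
      if (nx * ny > budget) next
      tab <- table(factor(naive_bins(xr, sort(xc)), levels = seq_len(nx)),
                   factor(naive_bins(yr, sort(yc)), levels = seq_len(ny)))
      val <- naive_mi(tab) / log2(min(nx, ny))
      if (val > best) best <- val
    }
  }
  best
}
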