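## Shared fixtures and independent brute-force oracles.
suppressPackageStartupMessages({
  library(GenomicRanges)
})

tiny_layout <- function(len = 10000, chroms = "chrT") {
  genome_layout(chroms, rep(len, length(chroms)))
}

## Random interval set on one chromosome, 0-based half-open coordinates.
random_intervals <- function(n, chrom_len, layout,
                             max_width = chrom_len %/% 10,
                             chrom = "chrT") {
  w <- sample.int(max_width, n, replace = TRUE)
  s <- floor(runif(n) * (chrom_len - w))
  bp_interval(rep(chrom, n), s, s + w, layout = layout)
}

## O(n^2) all-pairs total overlap length between two interval sets.
brute_overlap_bp <- function(a, b) {
  sa <- start(a); ea <- end(a); sb <- start(b); eb <- end(b)
  ca <- as.character(seqnames(a)); cb <- as.character(seqnames(b))
  tot <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (ca[i] != cb[j]) next
    ov <- min(ea[i], eb[j]) - max(sa[i], sb[j]) + 1
    if (ov > 0) tot <- tot + ov
  }
  tot
}

## Per-base boolean-union covered fraction of each target.
brute_coverage_fraction <- function(targets, query) {
  vapply(seq_along(targets), function(i) {
    pos <- start(targets)[i]:end(targets)[i]
    covered <- rep(FALSE, length(pos))
    same <- as.character(seqnames(query)) ==
      as.character(seqnames(targets))[i]
    for (j in which(same)) {
      covered <- covered | (pos >= start(query)[j] & pos <= end(query)[j])
    }
    mean(covered)
  }, numeric(1))
}

## Run-length-encoding domain oracle: maximal runs of selected bins.
rle_domains <- function(selected, bins) {
  r <- rle(selected)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (!length(keep)) return(bins[0])
  GRanges(seqnames(bins)[starts[keep]],
          IRanges(start(bins)[starts[keep]], end(bins)[ends[keep]]))
}

## 16-cell double-loop ISm oracle.
ism_oracle <- function(M, i, span = 4) {
  v <- c()
  for (du in seq_len(span)) for (dv in seq_len(span))
    v <- c(v, M[i - du, i + dv])
  mean(v[is.finite(v)])
}

## Exhaustive-partition Armatus oracle for small n; domain density sums
## interaction pairs k <= i < j <= l (no self-bin cells).
brute_tad_score <- function(L, gamma) {
  n <- nrow(L)
  u <- L; u[!is.finite(u)] <- 0; u[lower.tri(u, diag = TRUE)] <- 0
  ssum <- function(k, l) sum(u[k:l, k:l])
  mu <- sapply(seq_len(n), function(d)
    mean(sapply(seq_len(n - d + 1), function(k) ssum(k, k + d - 1) / d^gamma)))
  q <- function(k, l) ssum(k, l) / (l - k + 1)^gamma - mu[l - k + 1]
  best <- numeric(n + 1)
  for (j in seq_len(n)) {
    best[j + 1] <- best[j]
    for (k in seq_len(j)) {
      qq <- q(k, j)
      if (qq > 0) best[j + 1] <- max(best[j + 1], best[k] + qq)
    }
  }
  best[n + 1]
}

## Symmetric random matrix helpers.
random_symmetric <- function(n, gen = function(m) rexp(m)) {
  M <- matrix(gen(n * n), n)
  (M + t(M)) / 2
}

random_count_matrix <- function(n, lambda = 20) {
  M <- matrix(rpois(n * n, lambda), n)
  M + t(M)
}
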