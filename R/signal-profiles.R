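#' Averaged signal profile around anchor midpoints
#'
#' The signal in a window of `+-flank` bp around the midpoint of each anchor
#' is resampled to `out_bins` equal windows (area-weighted mean of the
#' overlapping source bins, masked bins excluded) and averaged over anchors.
#' Windows truncated by chromosome ends contribute only their defined
#' positions, so `n` can drop near ends but no anchor is discarded.
#'
#' @param track A [binned_track()].
#' @param anchors `GRanges` of anchor intervals.
#' @param flank Half-window in bp (> 0).
#' @param out_bins Number of output positions; defaults to one per source
#'   bin width.
#' @return `data.frame` of class `averaged_profile`: `position` (bp offset
#'   of each output-window center from the anchor midpoint), `mean`, `n`
#'   (anchors contributing).
#' @export
average_anchor_profile <- function(track, anchors, flank, out_bins = NULL) {
  if (length(anchors) == 0) stop("no anchors")
  if (flank <= 0) stop("flank must be > 0")
  if (is.null(out_bins))
    out_bins <- max(1L, round(2 * flank / track$bin_size))
  step <- 2 * flank / out_bins
  centers <- -flank + (seq_len(out_bins) - 0.5) * step

  mids <- mid_point(anchors)                    # 1-based midpoint coordinate
  chr <- as.character(GenomeInfoDb::seqnames(anchors))
  sums <- numeric(out_bins); wts <- numeric(out_bins)
  ncontrib <- integer(out_bins)
  for (cn in unique(chr)) {
    sel <- which(chr == cn)
    vals <- chrom_values(track, cn)
    for (i in sel) {
      ## output window k covers [m - flank + (k-1)*step, m - flank + k*step)
      ## in 0-based genomic bp
      a <- (mids[i] - 1) - flank + (seq_len(out_bins) - 1) * step
      b <- a + step
      wm <- window_weighted_means(vals, track$bin_size, a, b)
      ok <- is.finite(wm$mean) & wm$weight > 0
      sums[ok] <- sums[ok] + wm$mean[ok]
      wts[ok] <- wts[ok] + 1
      ncontrib[ok] <- ncontrib[ok] + 1L
    }
  }
  mean_v <- ifelse(wts > 0, sums / wts, NA_real_)
  structure(data.frame(position = centers, mean = mean_v, n = ncontrib),
            class = c("averaged_profile", "data.frame"))
}

chrom_values <- function(track, chrom) {
  track$values[track_chrom_idx(track, chrom)]
}

## Area-weighted means of a per-bin signal over arbitrary genomic windows
## [a, b) in 0-based bp on one chromosome. NA bins carry no weight; windows
## outside the chromosome contribute nothing.
window_weighted_means <- function(vals, bin_size, a, b) {
  n_bins <- length(vals)
  num <- numeric(length(a)); den <- numeric(length(a))
  i0 <- floor(a / bin_size)
  i1 <- ceiling(b / bin_size) - 1
  max_span <- max(i1 - i0) + 1
  for (j in seq_len(max_span) - 1) {
    idx <- i0 + j
    inside <- idx >= 0 & idx < n_bins & idx <= i1
    w <- pmax(pmin(b, (idx + 1) * bin_size) - pmax(a, idx * bin_size), 0)
    v <- rep(NA_real_, length(a))
    v[inside] <- vals[idx[inside] + 1]
    use <- inside & w > 0 & is.finite(v)
    num[use] <- num[use] + v[use] * w[use]
    den[use] <- den[use] + w[use]
  }
  list(mean = ifelse(den > 0, num / den, NA_real_), weight = den)
}

#' Metagene profile over rescaled gene bodies
#'
#' Each gene body is linearly rescaled to `body_bins` positions; flanks are
#' kept in genomic bp at the source bin width. Minus-strand genes are
#' reversed so all profiles run 5' to 3'. Values are area-weighted means of
#' source bins; the mean is taken over genes.
#'
#' @param track A [binned_track()].
#' @param genes Stranded `GRanges`; genes shorter than one source bin are
#'   dropped with a warning.
#' @param body_bins Number of positions across the gene body (default 100).
#' @param flank Flank length in bp on each side (default 2000).
#' @return `data.frame` of class `averaged_profile` with columns `x`
#'   (ordinal position), `section` (`upstream`/`body`/`downstream`),
#'   `position` (bp into flank, or fraction of body), `mean`, `n`.
#' @export
metagene_profile <- function(track, genes, body_bins = 100, flank = 2000) {
  if (length(genes) == 0) stop("empty gene set")
  short <- GenomicRanges::width(genes) < track$bin_size
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than one source bin dropped")
    genes <- genes[!short]
    if (length(genes) == 0) stop("no genes left after length filter")
  }
  B <- track$bin_size
  fb <- max(1L, round(flank / B))
  n_out <- 2L * fb + body_bins
  chr <- as.character(GenomeInfoDb::seqnames(genes))
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  gs0 <- GenomicRanges::start(genes) - 1      # 0-based
  ge0 <- GenomicRanges::end(genes)            # 0-based exclusive

  sums <- numeric(n_out); cnts <- numeric(n_out); ncontrib <- integer(n_out)
  for (i in seq_along(genes)) {
    vals <- chrom_values(track, chr[i])
    up_a <- gs0[i] - (fb:1) * B; up_b <- up_a + B
    body_edges <- seq(gs0[i], ge0[i], length.out = body_bins + 1)
    bo_a <- body_edges[-(body_bins + 1)]; bo_b <- body_edges[-1]
    dn_a <- ge0[i] + (seq_len(fb) - 1) * B; dn_b <- dn_a + B
    wm <- window_weighted_means(vals, B, c(up_a, bo_a, dn_a),
                                c(up_b, bo_b, dn_b))
    v <- wm$mean
    if (minus[i]) v <- rev(v)
    ok <- is.finite(v)
    sums[ok] <- sums[ok] + v[ok]
    cnts[ok] <- cnts[ok] + 1
    ncontrib[ok] <- ncontrib[ok] + 1L
  }
  section <- c(rep("upstream", fb), rep("body", body_bins),
               rep("downstream", fb))
  position <- c(-(fb:1) * B + B / 2,
                (seq_len(body_bins) - 0.5) / body_bins,
                (seq_len(fb) - 0.5) * B)
  structure(data.frame(x = seq_len(n_out), section = section,
                       position = position,
                       mean = ifelse(cnts > 0, sums / cnts, NA_real_),
                       n = ncontrib),
            class = c("averaged_profile", "data.frame"))
}

as_dna_set <- function(fasta) {
  if (inherits(fasta, "DNAStringSet")) return(fasta)
  if (is.character(fasta)) return(Biostrings::readDNAStringSet(fasta))
  stop("fasta must be a DNAStringSet or a FASTA file path")
}

#' A/T-content profile around anchors
#'
#' Percentage of A/T bases in consecutive `window`-bp windows across
#' `+-flank` bp around each anchor midpoint, averaged over anchors. N bases
#' are excluded from both numerator and denominator. Anchors whose window
#' leaves the sequence are skipped with a warning.
#'
#' @param fasta `DNAStringSet` or FASTA path; names must match chromosome
#'   names of the anchors.
#' @param anchors `GRanges`.
#' @param flank Half-window in bp.
#' @param window Window width in bp (default 20).
#' @return `averaged_profile` data.frame: `position` (window center offset),
#'   `mean` (percent A/T), `n`.
#' @export
at_content_profile <- function(fasta, anchors, flank, window = 20) {
  seqs <- as_dna_set(fasta)
  if (length(anchors) == 0) stop("no anchors")
  nw <- floor(2 * flank / window)
  span <- nw * window
  mids <- mid_point(anchors)
  chr <- as.character(GenomeInfoDb::seqnames(anchors))
  sums <- numeric(nw); cnts <- numeric(nw); skipped <- 0L
  for (i in seq_along(anchors)) {
    s1 <- mids[i] - span %/% 2 + 1          # 1-based inclusive
    e1 <- s1 + span - 1
    if (!chr[i] %in% names(seqs) || s1 < 1 ||
        e1 > length(seqs[[chr[i]]])) {
      skipped <- skipped + 1L
      next
    }
    sub <- Biostrings::subseq(seqs[[chr[i]]], s1, e1)
    m <- matrix(strsplit(as.character(sub), "")[[1]], nrow = window)
    at <- colSums(m == "A" | m == "T")
    nn <- colSums(m == "N")
    pct <- ifelse(window - nn > 0, 100 * at / (window - nn), NA_real_)
    ok <- is.finite(pct)
    sums[ok] <- sums[ok] + pct[ok]
    cnts[ok] <- cnts[ok] + 1
  }
  if (skipped > 0)
    warning(skipped, " anchor(s) skipped: window outside sequence")
  if (all(cnts == 0)) stop("no usable anchors")
  centers <- -span / 2 + (seq_len(nw) - 0.5) * window
  structure(data.frame(position = centers,
                       mean = ifelse(cnts > 0, sums / cnts, NA_real_),
                       n = as.integer(cnts)),
            class = c("averaged_profile", "data.frame"))
}

#' Fraction of sites containing an A/T-rich window near their center
#'
#' A site counts when at least one sliding `window`-bp window (1-bp step)
#' within `+-flank` bp of its midpoint has an A/T fraction of at least
#' `min_at_fraction`.
#'
#' @inheritParams at_content_profile
#' @param sites `GRanges`.
#' @param min_at_fraction A/T fraction threshold (default 0.9).
#' @return Percentage of sites (0-100).
#' @export
at_rich_fraction <- function(fasta, sites, flank = 150, window = 20,
                             min_at_fraction = 0.9) {
  seqs <- as_dna_set(fasta)
  if (length(sites) == 0) stop("empty site set")
  mids <- mid_point(sites)
  chr <- as.character(GenomeInfoDb::seqnames(sites))
  hit <- logical(length(sites)); usable <- logical(length(sites))
  for (i in seq_along(sites)) {
    s1 <- mids[i] - flank + 1
    e1 <- mids[i] + flank
    if (!chr[i] %in% names(seqs)) next
    L <- length(seqs[[chr[i]]])
    s1 <- max(1, s1); e1 <- min(L, e1)
    if (e1 - s1 + 1 < window) next
    usable[i] <- TRUE
    sub <- Biostrings::subseq(seqs[[chr[i]]], s1, e1)
    at <- Biostrings::letterFrequencyInSlidingView(sub, window, "AT")
    hit[i] <- any(at / window >= min_at_fraction)
  }
  if (!any(usable)) stop("no usable sites")
  100 * sum(hit[usable]) / sum(usable)
}
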