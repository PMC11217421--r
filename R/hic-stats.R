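#' Per-chromosome contact matrix
#'
#' Symmetric non-negative matrix of intra-chromosomal Hi-C contacts at a
#' fixed bin size, with a per-bin validity mask. Masked bins carry `NA`
#' rows/columns once balancing has been applied.
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp.
#' @param mat Symmetric numeric matrix.
#' @param valid Logical per-bin mask (`TRUE` = usable); defaults to all.
#' @param balanced Whether `mat` holds balanced (corrected) values.
#' @param transformed Allow negative values (for log-transformed
#'   matrices); contact counts are otherwise required non-negative.
#' @return Object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, bin_size, mat, valid = NULL,
                           balanced = FALSE, transformed = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("contact matrix must be square")
  if (bin_size <= 0) stop("bin_size must be > 0")
  fin <- is.finite(mat)
  if (!transformed && any(mat[fin] < 0))
    stop("contact counts must be non-negative")
  asym <- max(abs(mat[fin & t(fin)] - t(mat)[fin & t(fin)]), 0)
  if (asym > 1e-8 * (1 + max(abs(mat[fin]))))
    stop("contact matrix must be symmetric")
  if (is.null(valid)) valid <- rep(TRUE, nrow(mat))
  if (length(valid) != nrow(mat))
    stop("valid mask length must equal matrix dimension")
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 mat = mat, valid = valid, balanced = balanced),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$chrom, "-", nrow(x$mat), "bins of", x$bin_size,
      "bp;", sum(!x$valid), "masked;",
      if (x$balanced) "balanced" else "raw counts", "\n")
  invisible(x)
}

n_bins <- function(cm) nrow(cm$mat)

#' Read/write a COO contact list
#'
#' Plain tab-separated triplets `bin_i`, `bin_j`, `count` (0-based bin
#' indices, upper triangle), preceded by a header comment line
#' `# chrom=<name> bin_size=<bp> n_bins=<n>`.
#'
#' @param path File path.
#' @return A [contact_matrix()].
#' @export
read_contacts_coo <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "^#\\s*chrom=(\\S+)\\s+bin_size=(\\d+)\\s+n_bins=(\\d+)", hdr))[[1]]
  if (length(m) != 4)
    stop("missing or malformed COO header line in ", path)
  chrom <- m[2]; bin_size <- as.integer(m[3]); nb <- as.integer(m[4])
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("bin_i", "bin_j", "count"))
  if (any(tab$bin_i < 0 | tab$bin_j < 0 | tab$bin_i >= nb | tab$bin_j >= nb))
    stop("bin index outside matrix in ", path)
  mat <- matrix(0, nb, nb)
  i <- tab$bin_i + 1L; j <- tab$bin_j + 1L
  mat[cbind(i, j)] <- tab$count
  mat[cbind(j, i)] <- tab$count
  contact_matrix(chrom, bin_size, mat)
}

#' @rdname read_contacts_coo
#' @param cm A [contact_matrix()] to write.
#' @export
write_contacts_coo <- function(cm, path) {
  up <- which(upper.tri(cm$mat, diag = TRUE) & cm$mat != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chrom=%s bin_size=%d n_bins=%d",
                     cm$chrom, cm$bin_size, n_bins(cm)), con)
  utils::write.table(
    data.frame(bin_i = up[, 1] - 1L, bin_j = up[, 2] - 1L,
               count = cm$mat[up]),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove short-range contacts
#'
#' Zeroes all bin pairs whose midpoint separation (`|i - j| * bin_size`)
#' is below `min_separation`. At 2-kb bins with the default 1-kb cutoff
#' only the self-pairs (main diagonal) are affected.
#'
#' @param cm A [contact_matrix()].
#' @param min_separation Minimum retained separation in bp (default 1000).
#' @return A [contact_matrix()].
#' @export
remove_short_range <- function(cm, min_separation = 1000) {
  if (min_separation <= 0) return(cm)
  n <- n_bins(cm)
  sep <- abs(row(cm$mat) - col(cm$mat)) * cm$bin_size
  mat <- cm$mat
  mat[sep < min_separation] <- 0
  contact_matrix(cm$chrom, cm$bin_size, mat, cm$valid, cm$balanced)
}

#' Downsample a contact matrix by binomial thinning
#'
#' Each upper-triangle cell is thinned with `Binomial(count, target/total)`
#' and mirrored, so the expected total equals `target_total`.
#'
#' @param cm A raw-count [contact_matrix()].
#' @param target_total Target total contacts (upper triangle incl. diagonal).
#' @param seed Integer seed.
#' @return A [contact_matrix()].
#' @export
downsample_contacts <- function(cm, target_total, seed = 0) {
  tot <- sum(cm$mat[upper.tri(cm$mat, diag = TRUE)])
  if (target_total > tot)
    stop("target_total (", target_total, ") exceeds current total (",
         tot, ")")
  p <- target_total / tot
  seed <- as.integer(seed)  # force before the RNG snapshot (lazy args)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  up <- upper.tri(cm$mat, diag = TRUE)
  counts <- cm$mat[up]
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("downsampling requires integer counts")
  thinned <- stats::rbinom(length(counts), round(counts), p)
  mat <- matrix(0, n_bins(cm), n_bins(cm))
  mat[up] <- thinned
  mat <- mat + t(mat)
  diag(mat) <- diag(mat) / 2
  contact_matrix(cm$chrom, cm$bin_size, mat, cm$valid, FALSE)
}

#' Iterative correction (matrix balancing)
#'
#' Computes multiplicative per-bin biases such that all unmasked row sums
#' are equal. Bins with zero coverage, and bins whose coverage falls below
#' the `mask_quantile` quantile of positive coverages, are masked first and
#' excluded (their rows/columns become `NA`).
#'
#' @param cm A symmetric raw-count [contact_matrix()].
#' @param tol Relative row-sum tolerance (default 1e-6).
#' @param max_iter Maximum iterations (default 200).
#' @param mask_quantile Coverage quantile below which bins are masked
#'   (default 0.05).
#' @return A balanced [contact_matrix()] with attributes `biases` and
#'   `converged`.
#' @export
iterative_correction <- function(cm, tol = 1e-6, max_iter = 200,
                                 mask_quantile = 0.05) {
  n <- n_bins(cm)
  cov <- rowSums(cm$mat)
  valid <- cm$valid & cov > 0
  if (mask_quantile > 0 && any(valid)) {
    floor_cov <- stats::quantile(cov[valid], mask_quantile, names = FALSE)
    valid <- valid & cov >= floor_cov
  }
  if (sum(valid) < 2) stop("fewer than 2 valid bins after masking")
  sub <- cm$mat[valid, valid, drop = FALSE]
  bias <- rep(1, sum(valid))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(sub)
    r <- s / mean(s)
    if (max(abs(r - 1)) < tol) {
      converged <- TRUE
      break
    }
    r[r == 0] <- 1
    sub <- sub / outer(r, r)
    bias <- bias * r
  }
  if (!converged)
    warning("iterative correction did not converge in ", max_iter,
            " iterations; returning last iterate")
  mat <- matrix(NA_real_, n, n)
  mat[valid, valid] <- sub
  out <- contact_matrix(cm$chrom, cm$bin_size, mat, valid, TRUE)
  attr(out, "biases") <- bias
  attr(out, "converged") <- converged
  out
}

#' Expected contact frequency per separation
#'
#' Mean of unmasked cells at each bin separation `s = |i - j|`.
#'
#' @param cm A [contact_matrix()] (typically balanced).
#' @return Numeric vector of length `n_bins`, `expected[s + 1]` = mean
#'   contact at separation `s`; `NA` where no unmasked cell exists.
#' @export
expected_profile <- function(cm) {
  n <- n_bins(cm)
  out <- rep(NA_real_, n)
  for (s in 0:(n - 1)) {
    i <- seq_len(n - s)
    v <- cm$mat[cbind(i, i + s)]
    v <- v[is.finite(v)]
    if (length(v)) out[s + 1] <- mean(v)
  }
  out
}

#' Observed-over-expected contact matrix
#'
#' Each cell is divided by the mean contact at its separation, so every
#' diagonal of the result has unmasked mean 1. Separations with
#' non-positive or undefined expected values are masked.
#'
#' @param cm A balanced [contact_matrix()].
#' @return A [contact_matrix()] of O/E values.
#' @export
observed_over_expected <- function(cm) {
  n <- n_bins(cm)
  exp_s <- expected_profile(cm)
  sep <- abs(row(cm$mat) - col(cm$mat))
  e <- exp_s[sep + 1]
  e[!is.na(e) & e <= 0] <- NA_real_
  mat <- cm$mat / matrix(e, n, n)
  contact_matrix(cm$chrom, cm$bin_size, mat, cm$valid, TRUE)
}

#' Preprocess a balanced matrix for TAD calling
#'
#' Missing cells are linearly interpolated along each diagonal (diagonals
#' with fewer than two finite cells stay masked), values are clipped to the
#' 1st-99th percentile range of the finite cells, zeros are replaced by
#' half the smallest positive value, and the matrix is natural-log
#' transformed.
#'
#' @param cm A balanced [contact_matrix()].
#' @return A [contact_matrix()] of ln-transformed values with attribute
#'   `clip_range`.
#' @export
armatus_preprocess <- function(cm) {
  n <- n_bins(cm)
  mat <- cm$mat
  for (s in 0:(n - 1)) {
    i <- seq_len(n - s)
    idx <- cbind(i, i + s)
    v <- mat[idx]
    bad <- !is.finite(v)
    if (!any(bad)) next
    if (sum(!bad) >= 2) {
      v[bad] <- stats::approx(x = i[!bad], y = v[!bad], xout = i[bad],
                              rule = 1)$y
      mat[idx] <- v
      mat[idx[, c(2, 1), drop = FALSE]] <- v
    }
  }
  fin <- mat[is.finite(mat)]
  if (!length(fin)) stop("no finite cells to preprocess")
  qr <- stats::quantile(fin, c(0.01, 0.99), names = FALSE)
  mat[is.finite(mat) & mat < qr[1]] <- qr[1]
  mat[is.finite(mat) & mat > qr[2]] <- qr[2]
  pos <- mat[is.finite(mat) & mat > 0]
  zfill <- if (length(pos)) min(pos) / 2 else 1e-12
  mat[is.finite(mat) & mat == 0] <- zfill
  mat <- log(mat)
  out <- contact_matrix(cm$chrom, cm$bin_size, mat, cm$valid, TRUE,
                        transformed = TRUE)
  attr(out, "clip_range") <- qr
  out
}

## Rectangle sums of the zero-filled strict upper triangle via a
## summed-area table. s(k, l) = sum of interaction pairs k <= i < j <= l;
## self-bin (diagonal) cells carry no domain density.
upper_area_table <- function(mat) {
  u <- mat
  u[!is.finite(u)] <- 0
  u[lower.tri(u, diag = TRUE)] <- 0
  apply(apply(u, 2, cumsum), 1, cumsum)  # S[j, i] = sum rows<=i, cols<=j -> transposed
}

## s(k, l) for vectors k, l (1-based, k <= l) using table S where
## S[i, j] = sum of u[1:i, 1:j].
area_sum <- function(S, k, l) {
  n <- nrow(S)
  top <- ifelse(k > 1, S[cbind(pmax(k - 1, 1), l)], 0)
  left <- ifelse(k > 1, S[cbind(l, pmax(k - 1, 1))], 0)
  corner <- ifelse(k > 1, S[cbind(pmax(k - 1, 1), pmax(k - 1, 1))], 0)
  S[cbind(l, l)] - top - left + corner
}

#' Call TADs with the Armatus dynamic program
#'
#' Maximizes the summed quality `q(k, l) = s(k, l) / (l - k + 1)^gamma -
#' mu(l - k + 1)` over non-overlapping domains, where `s(k, l)` is the sum
#' of (preprocessed) matrix cells over interaction pairs `k <= i < j <= l`
#' (self-bin cells carry no domain density) and `mu(d)` is the mean scaled
#' density of all windows of size `d` on the chromosome. Only domains with
#' strictly positive quality (beyond numerical noise) are scored; gaps are
#' allowed. Ties are broken toward fewer domains.
#'
#' @param pre An [armatus_preprocess()]-ed (or otherwise transformed)
#'   [contact_matrix()].
#' @param gamma Resolution parameter (>= 0); larger gamma favors smaller
#'   domains.
#' @return `data.frame` of class `tad_set`: `start_bin`, `end_bin`
#'   (inclusive, 1-based), `start`, `end` (bp, 0-based half-open),
#'   `quality`; attribute `score` = total DP score.
#' @export
call_tads <- function(pre, gamma) {
  if (gamma < 0) stop("gamma must be >= 0")
  n <- n_bins(pre)
  S <- upper_area_table(pre$mat)
  fin <- pre$mat[is.finite(pre$mat)]
  q_tol <- 1e-9 * (1 + max(abs(fin), 0))  # float noise is not a domain
  sizes <- seq_len(n)
  mu <- numeric(n)
  for (d in sizes) {
    k <- seq_len(n - d + 1)
    mu[d] <- mean(area_sum(S, k, k + d - 1) / d^gamma)
  }
  best <- numeric(n + 1)   # best[j + 1] = optimum over bins 1..j
  choice <- integer(n + 1) # 0 = gap at j, k > 0 = domain [k, j]
  for (j in seq_len(n)) {
    best[j + 1] <- best[j]
    choice[j + 1] <- 0L
    k <- seq_len(j)
    d <- j - k + 1
    q <- area_sum(S, k, rep(j, j)) / d^gamma - mu[d]
    cand <- best[k] + q
    ok <- q > q_tol
    if (any(ok)) {
      ci <- which(ok)[which.max(cand[ok])]
      if (cand[ci] > best[j + 1]) {
        best[j + 1] <- cand[ci]
        choice[j + 1] <- ci
      }
    }
  }
  starts <- integer(0); ends <- integer(0); quals <- numeric(0)
  j <- n
  while (j > 0) {
    k <- choice[j + 1]
    if (k == 0) {
      j <- j - 1
    } else {
      d <- j - k + 1
      starts <- c(k, starts); ends <- c(j, ends)
      quals <- c(area_sum(S, k, j) / d^gamma - mu[d], quals)
      j <- k - 1
    }
  }
  out <- data.frame(start_bin = starts, end_bin = ends,
                    start = (starts - 1) * pre$bin_size,
                    end = ends * pre$bin_size,
                    quality = quals)
  attr(out, "score") <- best[n + 1]
  attr(out, "chrom") <- pre$chrom
  class(out) <- c("tad_set", "data.frame")
  out
}

#' Match TADs with identical boundaries between two sets
#'
#' @param tads_a,tads_b [call_tads()] outputs at the same bin size.
#' @return `data.frame` with indices `idx_a`, `idx_b` of pairs sharing
#'   identical `(start_bin, end_bin)`.
#' @export
match_tads <- function(tads_a, tads_b) {
  if (nrow(tads_a) == 0 || nrow(tads_b) == 0)
    return(data.frame(idx_a = integer(0), idx_b = integer(0)))
  key_a <- paste(tads_a$start_bin, tads_a$end_bin)
  key_b <- paste(tads_b$start_bin, tads_b$end_bin)
  m <- match(key_a, key_b)
  keep <- !is.na(m)
  data.frame(idx_a = which(keep), idx_b = m[keep])
}

#' Average contact frequency within a TAD
#'
#' Mean of unmasked off-diagonal O/E cells with both bins inside the TAD
#' (`i < j`); the self-ligation-dominated main diagonal is excluded.
#'
#' @param oe An [observed_over_expected()] matrix.
#' @param start_bin,end_bin Inclusive 1-based bin range of the TAD.
#' @return Mean O/E, or `NA` (with a warning) for one-bin TADs.
#' @export
tad_acf <- function(oe, start_bin, end_bin) {
  if (end_bin - start_bin < 1) {
    warning("one-bin TAD: ACF undefined")
    return(NA_real_)
  }
  idx <- start_bin:end_bin
  sub <- oe$mat[idx, idx, drop = FALSE]
  v <- sub[upper.tri(sub)]
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Per-TAD log2 fold change of ACF between two conditions
#'
#' @param oe_kd,oe_ctrl O/E matrices for the two conditions.
#' @param tads A [call_tads()] output (e.g. the shared TADs).
#' @return `data.frame`: `start_bin`, `end_bin`, `acf_kd`, `acf_ctrl`,
#'   `log2fc`.
#' @export
acf_log2fc <- function(oe_kd, oe_ctrl, tads) {
  acf_kd <- mapply(function(s, e) tad_acf(oe_kd, s, e),
                   tads$start_bin, tads$end_bin)
  acf_ctrl <- mapply(function(s, e) tad_acf(oe_ctrl, s, e),
                     tads$start_bin, tads$end_bin)
  data.frame(start_bin = tads$start_bin, end_bin = tads$end_bin,
             acf_kd = acf_kd, acf_ctrl = acf_ctrl,
             log2fc = log2(acf_kd / acf_ctrl))
}

#' Group TADs by LAD vs active-chromatin content
#'
#' `Jacc = (X - Y) / (X + Y)` with `X` = fraction of the TAD covered by
#' LADs and `Y` = fraction covered by active chromatin; `Jacc` is defined
#' as 0 when `X + Y = 0`. Groups: `A` (active) when `Jacc < -0.8`, `C`
#' (inactive) when `Jacc > 0.8`, else `B`.
#'
#' @param tads [call_tads()] output carrying a `chrom` attribute, or a
#'   `data.frame` with `start`/`end` bp columns plus `chrom`.
#' @param lads,active `GRanges` of LADs and active-chromatin domains.
#' @param layout A [genome_layout()].
#' @param chrom Chromosome of the TADs (defaults to the `chrom` attribute).
#' @param threshold Group threshold on |Jacc| (default 0.8).
#' @return `data.frame`: TAD columns plus `X`, `Y`, `jacc`, `group`.
#' @export
jaccard_group <- function(tads, lads, active, layout,
                          chrom = attr(tads, "chrom"), threshold = 0.8) {
  if (nrow(tads) == 0)
    return(cbind(tads, X = numeric(0), Y = numeric(0),
                 jacc = numeric(0), group = character(0)))
  gr <- bp_interval(rep(chrom, nrow(tads)), tads$start, tads$end,
                    layout = layout)
  X <- coverage_fraction(gr, lads)
  Y <- coverage_fraction(gr, active)
  jacc <- ifelse(X + Y == 0, 0, (X - Y) / (X + Y))
  group <- ifelse(jacc < -threshold, "A",
                  ifelse(jacc > threshold, "C", "B"))
  cbind(tads, X = X, Y = Y, jacc = jacc, group = group)
}

#' Modified insulation score
#'
#' `ISm(i)` is the mean distance-normalized contact frequency within the
#' 8-kb square starting at the second diagonal: O/E cells `[u, v]` with
#' `u` in `i-4 .. i-1` and `v` in `i+1 .. i+4` at 2-kb resolution, i.e.
#' only contacts between regions 2-8 kb away on both sides of the central
#' bin. Contacts of the central bin itself and first-diagonal contacts are
#' excluded. Undefined near chromosome edges and where all 16 cells are
#' masked.
#'
#' @param oe An O/E [contact_matrix()] at 2-kb resolution.
#' @param span Square side in bins (default 4).
#' @param required_bin_size Expected resolution (default 2000); a
#'   mismatching matrix is an error.
#' @return Numeric vector, one value per bin (`NA` where undefined).
#' @export
ism_profile <- function(oe, span = 4, required_bin_size = 2000) {
  if (!is.null(required_bin_size) && oe$bin_size != required_bin_size)
    stop("ism_profile expects ", required_bin_size, "-bp bins, got ",
         oe$bin_size)
  n <- n_bins(oe)
  out <- rep(NA_real_, n)
  if (n < 2 * span + 1) return(out)
  acc <- matrix(0, n, 2)  # sums and counts
  for (du in seq_len(span)) {
    for (dv in seq_len(span)) {
      i <- (span + 1):(n - span)
      v <- oe$mat[cbind(i - du, i + dv)]
      ok <- is.finite(v)
      acc[i[ok], 1] <- acc[i[ok], 1] + v[ok]
      acc[i[ok], 2] <- acc[i[ok], 2] + 1
    }
  }
  i <- (span + 1):(n - span)
  out[i] <- ifelse(acc[i, 2] > 0, acc[i, 1] / acc[i, 2], NA_real_)
  out
}

#' Anchor-averaged ISm curve with linear-interpolation smoothing
#'
#' The ISm profile is cut into windows of `+-flank_bins` around each anchor
#' bin; undefined positions inside a window are filled by linear
#' interpolation between the nearest defined neighbors before averaging
#' across anchors.
#'
#' @param ism Per-bin ISm vector (from [ism_profile()]).
#' @param bin_size Bin width in bp of the ISm profile.
#' @param anchors `GRanges` of anchor sites (midpoints mapped to bins), or
#'   an integer vector of 1-based anchor bin indices.
#' @param flank_bins Half-window in bins.
#' @return `averaged_profile` data.frame: `position` (bp offset), `mean`,
#'   `n`.
#' @export
averaged_ism_around <- function(ism, bin_size, anchors, flank_bins) {
  if (inherits(anchors, "GRanges")) {
    abin <- (mid_point(anchors) - 1) %/% bin_size + 1
  } else {
    abin <- as.integer(anchors)
  }
  abin <- abin[abin - flank_bins >= 1 & abin + flank_bins <= length(ism)]
  if (!length(abin)) stop("no anchors with a full window")
  width <- 2 * flank_bins + 1
  sums <- numeric(width); cnts <- integer(width)
  for (a in abin) {
    w <- ism[(a - flank_bins):(a + flank_bins)]
    ok <- is.finite(w)
    if (sum(ok) >= 2) {
      w[!ok] <- stats::approx(x = which(ok), y = w[ok],
                              xout = which(!ok), rule = 1)$y
    }
    use <- is.finite(w)
    sums[use] <- sums[use] + w[use]
    cnts[use] <- cnts[use] + 1L
  }
  structure(data.frame(
    position = (-flank_bins:flank_bins) * bin_size,
    mean = ifelse(cnts > 0, sums / cnts, NA_real_),
    n = cnts),
    class = c("averaged_profile", "data.frame"))
}

#' Compartment eigenvector (PC1)
#'
#' First eigenvector of the Pearson correlation matrix of the O/E rows
#' (masked bins excluded). The sign is oriented so that positive values
#' correlate positively with `orientation` (e.g. gene expression or active
#' chromatin density), matching the A-positive convention.
#'
#' @param oe An O/E [contact_matrix()] (>= 20 unmasked bins).
#' @param orientation Numeric per-bin track used only to fix the sign.
#' @return Numeric per-bin PC1 (`NA` on masked bins) with attribute
#'   `degenerate` (TRUE when the matrix has no variance to decompose).
#' @export
compartment_pc1 <- function(oe, orientation) {
  n <- n_bins(oe)
  if (length(orientation) != n)
    stop("orientation must have one value per bin")
  valid <- oe$valid & apply(is.finite(oe$mat), 1, any)
  if (sum(valid) < 20) stop("need >= 20 unmasked bins")
  sub <- oe$mat[valid, valid, drop = FALSE]
  sds <- apply(sub, 1, stats::sd, na.rm = TRUE)
  if (all(!is.finite(sds)) || all(sds[is.finite(sds)] < 1e-12)) {
    out <- rep(NA_real_, n)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  keep <- is.finite(sds) & sds > 1e-12
  cc <- suppressWarnings(stats::cor(t(sub[keep, , drop = FALSE]),
                                    use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  ev <- eigen(cc, symmetric = TRUE)
  pc1 <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0))
  full <- rep(NA_real_, n)
  full[which(valid)[keep]] <- pc1
  ori <- suppressWarnings(stats::cor(full, orientation,
                                     use = "pairwise.complete.obs"))
  if (is.finite(ori) && ori < 0) full <- -full
  attr(full, "degenerate") <- FALSE
  full
}

#' Saddle plot: O/E averaged in PC1 quantile pairs
#'
#' Bins are ranked by PC1, the extreme `trim` fraction is dropped at each
#' end, the rest are digitized into `n_quantiles` equal-count groups
#' (ascending PC1: quantile 1 = strongest B, quantile `n_quantiles` =
#' strongest A), and each grid cell is the mean O/E over bin pairs in the
#' two groups.
#'
#' @param oe An O/E [contact_matrix()].
#' @param pc1 Per-bin PC1 values.
#' @param n_quantiles Number of quantile groups (default 50).
#' @param trim Fraction of extreme-PC1 bins dropped at each end
#'   (default 0.01).
#' @return List of class `saddle_result`: `grid` (n_quantiles x
#'   n_quantiles), `n_quantiles`, `trim`, `assignment` (per-bin quantile,
#'   `NA` for dropped/masked bins).
#' @export
saddle <- function(oe, pc1, n_quantiles = 50, trim = 0.01) {
  n <- n_bins(oe)
  ok <- is.finite(pc1) & oe$valid
  if (sum(ok) < n_quantiles) stop("fewer usable bins than quantiles")
  idx <- which(ok)
  r <- rank(pc1[idx], ties.method = "first")
  m <- length(idx)
  n_drop <- floor(trim * m)
  keep <- r > n_drop & r <= m - n_drop
  idx <- idx[keep]; r <- rank(pc1[idx], ties.method = "first")
  m <- length(idx)
  if (m < n_quantiles) stop("fewer usable bins than quantiles after trim")
  qt <- ceiling(r / m * n_quantiles)
  assignment <- rep(NA_integer_, n)
  assignment[idx] <- qt
  grid <- matrix(NA_real_, n_quantiles, n_quantiles)
  counts <- matrix(0L, n_quantiles, n_quantiles)
  sums <- matrix(0, n_quantiles, n_quantiles)
  sub <- oe$mat[idx, idx, drop = FALSE]
  fin <- is.finite(sub)
  qi <- matrix(qt, m, m); qj <- t(qi)
  for (cell in which(fin)) {
    a <- qi[cell]; b <- qj[cell]
    sums[a, b] <- sums[a, b] + sub[cell]
    counts[a, b] <- counts[a, b] + 1L
  }
  grid[counts > 0] <- sums[counts > 0] / counts[counts > 0]
  structure(list(grid = grid, n_quantiles = n_quantiles, trim = trim,
                 assignment = assignment),
            class = "saddle_result")
}

#' Compartment-block differences between two saddles
#'
#' Collects `KD - ctrl` grid cells in the `k` highest-PC1 quantile block
#' (AA, A-positive convention), the `k` lowest block (BB), and the two off
#' blocks (AB), each with a two-sided Wilcoxon signed-rank test against 0.
#'
#' @param saddle_kd,saddle_ctrl [saddle()] results with equal
#'   `n_quantiles`.
#' @param k Number of extreme quantiles per block (default 10).
#' @return List: `AA`, `BB`, `AB` (difference-cell vectors), `summary`
#'   data.frame (`block`, `n`, `mean`, `median`, `p_wilcoxon`).
#' @export
saddle_difference_summary <- function(saddle_kd, saddle_ctrl, k = 10) {
  nq <- saddle_kd$n_quantiles
  if (saddle_ctrl$n_quantiles != nq)
    stop("saddles have different numbers of quantiles")
  if (nq < 2 * k) stop("n_quantiles must be >= 2k")
  D <- saddle_kd$grid - saddle_ctrl$grid
  lo <- seq_len(k); hi <- (nq - k + 1):nq
  bb <- D[lo, lo]; aa <- D[hi, hi]
  ab <- c(D[lo, hi], D[hi, lo])
  blocks <- list(AA = aa[is.finite(aa)], BB = bb[is.finite(bb)],
                 AB = ab[is.finite(ab)])
  rows <- lapply(names(blocks), function(b) {
    v <- blocks[[b]]
    p <- if (!length(v) || all(v == 0)) 1 else
      suppressWarnings(stats::wilcox.test(v, mu = 0)$p.value)
    data.frame(block = b, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               p_wilcoxon = p)
  })
  c(blocks, list(summary = do.call(rbind, rows)))
}

#' Anchor-centered average O/E submatrix (pileup)
#'
#' Element-wise mean of the `(2*flank_bins + 1)^2` O/E windows centered on
#' each anchor's bin; anchors whose window leaves the chromosome are
#' skipped.
#'
#' @param oe An O/E [contact_matrix()].
#' @param anchors `GRanges` (midpoints mapped to bins) or 1-based bin
#'   indices.
#' @param flank_bins Half-window in bins.
#' @return List of class `pileup`: `grid` (mean window), `n_anchors`.
#' @export
pileup_oe <- function(oe, anchors, flank_bins) {
  if (inherits(anchors, "GRanges")) {
    abin <- (mid_point(anchors) - 1) %/% oe$bin_size + 1
  } else {
    abin <- as.integer(anchors)
  }
  n <- n_bins(oe)
  abin <- abin[abin - flank_bins >= 1 & abin + flank_bins <= n]
  if (!length(abin)) stop("no anchors with a full window")
  width <- 2 * flank_bins + 1
  sums <- matrix(0, width, width); cnts <- matrix(0L, width, width)
  for (a in abin) {
    w <- oe$mat[(a - flank_bins):(a + flank_bins),
                (a - flank_bins):(a + flank_bins)]
    ok <- is.finite(w)
    sums[ok] <- sums[ok] + w[ok]
    cnts[ok] <- cnts[ok] + 1L
  }
  grid <- matrix(NA_real_, width, width)
  grid[cnts > 0] <- sums[cnts > 0] / cnts[cnts > 0]
  structure(list(grid = grid, n_anchors = length(abin)),
            class = "pileup")
}

#' Difference of two pileups
#'
#' @param pileup_kd,pileup_ctrl [pileup_oe()] results of equal size.
#' @return Matrix `pileup_kd$grid - pileup_ctrl$grid`.
#' @export
pileup_difference <- function(pileup_kd, pileup_ctrl) {
  pileup_kd$grid - pileup_ctrl$grid
}

#' Aggregate a contact matrix to a coarser resolution
#'
#' Sums counts in `factor x factor` blocks (e.g. 2-kb to 4-kb maps for TAD
#' calling, 2-kb to 10-kb for compartments). Raw counts only.
#'
#' @param cm A raw-count [contact_matrix()].
#' @param factor Integer aggregation factor.
#' @return A [contact_matrix()] at `bin_size * factor`.
#' @export
rebin_contacts <- function(cm, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(cm)
  n <- n_bins(cm)
  n_new <- ceiling(n / factor)
  grp <- rep(seq_len(n_new), each = factor)[seq_len(n)]
  agg <- rowsum(cm$mat, grp)
  agg <- t(rowsum(t(agg), grp))
  contact_matrix(cm$chrom, cm$bin_size * factor, agg, balanced = FALSE)
}
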