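#' Nuclear radius from volume
#'
#' Assumes a spherical nucleus: `r = (3V / 4 pi)^(1/3)`.
#'
#' @param volume Volume(s) in cubic micrometres (> 0).
#' @return Radius in micrometres.
#' @export
radius_from_volume <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volume must be strictly positive")
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Radial-normalized locus-to-envelope distances
#'
#' Divides each locus-to-nuclear-envelope distance by the nuclear radius
#' inferred from the nucleus volume. Values above 1 (reconstruction noise)
#' are retained but flagged with a warning.
#'
#' @param distances Distances in micrometres (>= 0).
#' @param volume Nucleus volume in cubic micrometres.
#' @return Numeric vector of dimensionless distances, attribute `flagged`
#'   marking values > 1.
#' @export
normalized_radial_distance <- function(distances, volume) {
  if (any(distances < 0)) stop("distances must be non-negative")
  r <- radius_from_volume(volume)
  out <- distances / r
  flagged <- out > 1
  if (any(flagged))
    warning(sum(flagged), " normalized distance(s) exceed 1 ",
            "(kept, flagged)")
  attr(out, "flagged") <- flagged
  out
}

#' Compare two distance distributions (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with tie correction,
#' plus group medians.
#'
#' @param a,b Numeric samples (n >= 3 each).
#' @return List: `p_value`, `median_a`, `median_b`, `n_a`, `n_b`,
#'   `statistic`.
#' @export
compare_distance_distributions <- function(a, b) {
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 observations per group")
  ht <- suppressWarnings(stats::wilcox.test(a, b))
  list(p_value = ht$p.value, median_a = stats::median(a),
       median_b = stats::median(b), n_a = length(a), n_b = length(b),
       statistic = unname(ht$statistic))
}

## Locate the nuclear-envelope marker peaks: argmax within each outer third
## of the profile. Returns NULL when detection is degenerate.
ne_peaks <- function(ne) {
  n <- length(ne)
  if (diff(range(ne)) < sqrt(.Machine$double.eps)) return(NULL)
  third <- max(1L, floor(n / 3))
  p1 <- which.max(ne[seq_len(third)])
  p2 <- (n - third) + which.max(ne[(n - third + 1):n])
  if (p2 - p1 < 2) return(NULL)
  c(p1, p2)
}

#' Align diameter intensity profiles on envelope peaks and average
#'
#' Each profile is divided by its own mean intensity, its position axis is
#' rescaled so the two envelope-marker peaks map to 0 and 1, and the signal
#' is resampled to `out_points` positions before averaging across nuclei.
#' Profiles whose envelope peaks cannot be located are skipped with a
#' warning. The result is invariant to uniform intensity scaling of any
#' input profile.
#'
#' @param profiles List of profiles; each a list with numeric elements
#'   `signal` (the chromatin channel) and `ne` (the envelope-marker
#'   channel), sampled at the same positions (>= 16 samples).
#' @param out_points Number of output positions (default 100).
#' @return `averaged_profile` data.frame: `position` (0 = one envelope
#'   peak, 1 = the other), `mean`, `n`.
#' @export
align_and_average_profiles <- function(profiles, out_points = 100) {
  if (!length(profiles)) stop("no profiles")
  xout <- seq(0, 1, length.out = out_points)
  sums <- numeric(out_points); cnts <- integer(out_points); skipped <- 0L
  for (p in profiles) {
    if (length(p$signal) < 16 || length(p$signal) != length(p$ne)) {
      skipped <- skipped + 1L
      next
    }
    pk <- ne_peaks(p$ne)
    if (is.null(pk)) {
      skipped <- skipped + 1L
      next
    }
    sig <- p$signal / mean(p$signal)
    x <- (seq_along(sig) - pk[1]) / (pk[2] - pk[1])
    v <- stats::approx(x, sig, xout = xout, rule = 1)$y
    ok <- is.finite(v)
    sums[ok] <- sums[ok] + v[ok]
    cnts[ok] <- cnts[ok] + 1L
  }
  if (skipped > 0)
    warning(skipped, " profile(s) skipped (peak detection failed or too ",
            "few samples)")
  if (all(cnts == 0)) stop("no usable profiles")
  structure(data.frame(position = xout,
                       mean = ifelse(cnts > 0, sums / cnts, NA_real_),
                       n = cnts),
            class = c("averaged_profile", "data.frame"))
}

## Per-nucleus mean normalized intensity within the peripheral zone
## [0, zone] and [1 - zone, 1] of its aligned profile.
peripheral_zone_means <- function(profiles, zone, out_points = 100) {
  xout <- seq(0, 1, length.out = out_points)
  in_zone <- xout <= zone | xout >= 1 - zone
  vapply(profiles, function(p) {
    pk <- ne_peaks(p$ne)
    if (is.null(pk)) return(NA_real_)
    sig <- p$signal / mean(p$signal)
    x <- (seq_along(sig) - pk[1]) / (pk[2] - pk[1])
    v <- stats::approx(x, sig, xout = xout, rule = 1)$y
    mean(v[in_zone], na.rm = TRUE)
  }, numeric(1))
}

#' Peripheral-zone intensity test between two conditions
#'
#' Summarizes each nucleus by its mean aligned, intensity-normalized signal
#' within radial positions `[0, zone]` from each envelope end, then
#' compares the two conditions with a two-sided Mann-Whitney U test
#' (per-nucleus summaries avoid pseudo-replication of pixels).
#'
#' @param profiles_a,profiles_b Profile lists as in
#'   [align_and_average_profiles()].
#' @param zone Peripheral zone as a fraction of the diameter half
#'   (default 0.15); must lie in (0, 0.5).
#' @param out_points Resampling resolution (default 100).
#' @return List: `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `zone_means_a`, `zone_means_b`.
#' @export
peripheral_zone_test <- function(profiles_a, profiles_b, zone = 0.15,
                                 out_points = 100) {
  if (zone <= 0 || zone >= 0.5) stop("zone must lie in (0, 0.5)")
  za <- peripheral_zone_means(profiles_a, zone, out_points)
  zb <- peripheral_zone_means(profiles_b, zone, out_points)
  za <- za[is.finite(za)]; zb <- zb[is.finite(zb)]
  if (length(za) < 3 || length(zb) < 3)
    stop("need at least 3 usable nuclei per condition")
  ht <- suppressWarnings(stats::wilcox.test(za, zb))
  list(p_value = ht$p.value, mean_a = mean(za), mean_b = mean(zb),
       n_a = length(za), n_b = length(zb),
       zone_means_a = za, zone_means_b = zb)
}
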