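#' Normalize DamID counts to a log2(fusion/Dam) track
#'
#' Replicate count tracks are summed per bin (replicates are merged at the
#' read level), a pseudocount is added to the raw counts of both samples,
#' each sample is scaled to reads per million (RPM) of its own total, and
#' the per-bin log2 ratio fusion/Dam is taken. Bins where the Dam sample has
#' zero adjusted counts are masked. The result is invariant to uniform
#' scaling of all counts within one sample.
#'
#' @param fusion_reps A [binned_track()] of Dam-fusion counts, or a list of
#'   replicate tracks.
#' @param dam_reps A [binned_track()] of Dam-only counts, or a list of
#'   replicate tracks.
#' @param pseudocount Raw counts added to every bin of both samples before
#'   RPM conversion (default 1; use 0 to reproduce plain ratios).
#' @param cor_warn Warn when the Pearson correlation between replicates on
#'   jointly unmasked bins falls below this threshold (default 0.8).
#' @return List of class `damid_norm` with elements `log2_ratio`,
#'   `fusion_rpm`, `dam_rpm` (binned tracks), `pseudocount` and
#'   `replicate_cor`.
#' @export
normalize_damid <- function(fusion_reps, dam_reps, pseudocount = 1,
                            cor_warn = 0.8) {
  fusion_reps <- as_track_list(fusion_reps)
  dam_reps <- as_track_list(dam_reps)
  ref <- fusion_reps[[1]]
  all_tracks <- c(fusion_reps, dam_reps)
  for (tr in all_tracks) {
    if (!identical(layout_lengths(tr$layout), layout_lengths(ref$layout)) ||
        tr$bin_size != ref$bin_size)
      stop("all count tracks must share one layout and bin size")
  }
  rep_cor <- c(fusion = replicate_cor(fusion_reps),
               dam = replicate_cor(dam_reps))
  low <- rep_cor[!is.na(rep_cor) & rep_cor < cor_warn]
  if (length(low))
    warning("replicate correlation below ", cor_warn, " for: ",
            paste(names(low), round(low, 3), collapse = ", "))

  fusion <- merge_counts(fusion_reps)
  dam <- merge_counts(dam_reps)
  if (sum(fusion, na.rm = TRUE) == 0 || sum(dam, na.rm = TRUE) == 0)
    stop("all-zero count sample")
  fusion <- fusion + pseudocount
  dam <- dam + pseudocount
  fusion_rpm <- fusion / sum(fusion, na.rm = TRUE) * 1e6
  dam_rpm <- dam / sum(dam, na.rm = TRUE) * 1e6
  ratio <- log2(fusion_rpm / dam_rpm)
  ratio[!is.finite(ratio)] <- NA_real_
  ratio[is.na(dam_rpm) | dam_rpm == 0] <- NA_real_
  layout <- ref$layout; bs <- ref$bin_size
  structure(list(log2_ratio = binned_track(layout, bs, ratio),
                 fusion_rpm = binned_track(layout, bs, fusion_rpm),
                 dam_rpm = binned_track(layout, bs, dam_rpm),
                 pseudocount = pseudocount,
                 replicate_cor = rep_cor),
            class = "damid_norm")
}

as_track_list <- function(x) {
  if (inherits(x, "binned_track")) list(x) else x
}

replicate_cor <- function(tracks) {
  if (length(tracks) < 2) return(NA_real_)
  v1 <- tracks[[1]]$values; v2 <- tracks[[2]]$values
  ok <- is.finite(v1) & is.finite(v2)
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(v1[ok], v2[ok])
}

merge_counts <- function(tracks) {
  vals <- vapply(tracks, function(t) {
    v <- t$values; v[is.na(v)] <- 0; v
  }, numeric(length(tracks[[1]]$values)))
  if (is.null(dim(vals))) vals else rowSums(vals)
}

#' Fit a Gaussian hidden Markov model to a log-ratio track
#'
#' Segments the per-bin signal into `n_states` levels with a Gaussian-emission
#' HMM fit by expectation-maximization (Baum-Welch) and decoded by the
#' most-probable (Viterbi) path. Masked bins split the chain: each maximal
#' run of valid bins within a chromosome is an independent sequence sharing
#' one parameter set. Emission means are initialized at empirical quantiles
#' of the unmasked values (2 states: 25th/75th percentile; 3 states:
#' 10th/50th/90th), which makes the fit deterministic; states are
#' canonicalized by ascending emission mean.
#'
#' @param track A [binned_track()] (typically a DamID log2 ratio).
#' @param n_states 2 or 3.
#' @param seed Unused by the deterministic initialization; kept so callers
#'   can thread one seed through a pipeline stage.
#' @param max_iter,tol EM stopping rule: stop when the relative log-likelihood
#'   gain drops below `tol` or after `max_iter` iterations.
#' @param var_floor Variance floor as a fraction of the overall signal
#'   variance; flooring is flagged in the result.
#' @return List of class `hmm_fit`: `n_states`, `means`, `vars`,
#'   `transition`, `initial`, `loglik`, `states` (per-bin decoded state,
#'   `NA` on masked bins), `converged`, `var_floored`.
#' @export
fit_hmm <- function(track, n_states = 2, seed = 0, max_iter = 100,
                    tol = 1e-6, var_floor = 1e-4) {
  if (!n_states %in% c(2L, 3L)) stop("n_states must be 2 or 3")
  x <- track$values
  ok <- is.finite(x)
  if (sum(ok) < 10 * n_states)
    stop("need at least ", 10 * n_states, " unmasked bins")
  segs <- valid_segments(track)
  xs <- lapply(segs, function(idx) x[idx])

  probs <- if (n_states == 2) c(0.25, 0.75) else c(0.1, 0.5, 0.9)
  mu <- as.numeric(stats::quantile(x[ok], probs, names = FALSE))
  v0 <- stats::var(x[ok])
  if (!is.finite(v0) || v0 <= 0) v0 <- 1e-6
  sig2 <- rep(v0, n_states)
  floor_v <- var_floor * v0
  K <- n_states
  A <- matrix(0.05 / (K - 1), K, K); diag(A) <- 0.95
  pi0 <- rep(1 / K, K)

  loglik <- -Inf; converged <- FALSE; floored <- FALSE
  for (it in seq_len(max_iter)) {
    ll <- 0
    g_sum <- numeric(K); g_x <- numeric(K); g_x2 <- numeric(K)
    xi_sum <- matrix(0, K, K); pi_acc <- numeric(K)
    per_seg <- vector("list", length(xs))
    for (si in seq_along(xs)) {
      fb <- hmm_forward_backward(xs[[si]], mu, sig2, A, pi0)
      ll <- ll + fb$loglik
      g <- fb$gamma
      g_sum <- g_sum + colSums(g)
      g_x <- g_x + as.numeric(crossprod(g, xs[[si]]))
      g_x2 <- g_x2 + as.numeric(crossprod(g, xs[[si]]^2))
      xi_sum <- xi_sum + fb$xi
      pi_acc <- pi_acc + g[1, ]
      per_seg[[si]] <- fb
    }
    mu_new <- g_x / g_sum
    sig2_new <- g_x2 / g_sum - mu_new^2
    if (any(sig2_new < floor_v)) {
      floored <- TRUE
      sig2_new <- pmax(sig2_new, floor_v)
    }
    denom <- rowSums(xi_sum)
    A_new <- A
    pos <- denom > 0
    A_new[pos, ] <- xi_sum[pos, , drop = FALSE] / denom[pos]
    pi_new <- pi_acc / sum(pi_acc)

    if (is.finite(loglik) && abs(ll - loglik) < tol * (abs(loglik) + 1)) {
      converged <- TRUE
      mu <- mu_new; sig2 <- sig2_new; A <- A_new; pi0 <- pi_new
      loglik <- ll
      break
    }
    mu <- mu_new; sig2 <- sig2_new; A <- A_new; pi0 <- pi_new
    loglik <- ll
  }

  ord <- order(mu)
  mu <- mu[ord]; sig2 <- sig2[ord]
  A <- A[ord, ord, drop = FALSE]; pi0 <- pi0[ord]

  states <- rep(NA_integer_, length(x))
  for (si in seq_along(segs))
    states[segs[[si]]] <- hmm_viterbi(xs[[si]], mu, sig2, A, pi0)

  structure(list(n_states = K, means = mu, vars = sig2, transition = A,
                 initial = pi0, loglik = loglik, states = states,
                 converged = converged, var_floored = floored,
                 bin_size = track$bin_size, layout = track$layout),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("Gaussian HMM,", x$n_states, "states; loglik", round(x$loglik, 2),
      if (!x$converged) "(not converged)" else "", "\n")
  cat("  means:", paste(round(x$means, 3), collapse = ", "), "\n")
  cat("  sds:  ", paste(round(sqrt(x$vars), 3), collapse = ", "), "\n")
  invisible(x)
}

## Maximal runs of valid bins, split at chromosome boundaries and mask gaps.
valid_segments <- function(track) {
  chr <- as.character(GenomeInfoDb::seqnames(track$bins))
  ok <- is.finite(track$values)
  n <- length(ok)
  if (n == 0) return(list())
  new_run <- ok & (!c(FALSE, ok[-n]) | chr != c("", chr[-n]))
  run_id <- cumsum(new_run)
  run_id[!ok] <- 0L
  idx <- which(ok)
  unname(split(idx, run_id[idx]))
}

gauss_dens <- function(x, mu, sig2) {
  K <- length(mu)
  d <- vapply(seq_len(K),
              function(k) stats::dnorm(x, mu[k], sqrt(sig2[k])),
              numeric(length(x)))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  d[d < 1e-300] <- 1e-300
  d
}

## Scaled forward-backward for one sequence; returns gamma (T x K),
## summed xi (K x K) and the log-likelihood.
hmm_forward_backward <- function(x, mu, sig2, A, pi0) {
  Tn <- length(x); K <- length(mu)
  B <- gauss_dens(x, mu, sig2)
  alpha <- matrix(0, Tn, K); beta <- matrix(0, Tn, K)
  cscale <- numeric(Tn)
  a <- pi0 * B[1, ]
  cscale[1] <- sum(a); alpha[1, ] <- a / cscale[1]
  if (Tn > 1) for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% A) * B[t, ]
    cscale[t] <- sum(a)
    alpha[t, ] <- a / cscale[t]
  }
  beta[Tn, ] <- 1
  if (Tn > 1) for (t in (Tn - 1):1) {
    b <- A %*% (B[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / cscale[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, K, K)
  if (Tn > 1) for (t in 1:(Tn - 1)) {
    m <- outer(alpha[t, ], B[t + 1, ] * beta[t + 1, ]) * A
    xi <- xi + m / sum(m)
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cscale)))
}

hmm_viterbi <- function(x, mu, sig2, A, pi0) {
  Tn <- length(x); K <- length(mu)
  logB <- log(gauss_dens(x, mu, sig2))
  logA <- log(A)
  delta <- matrix(-Inf, Tn, K); psi <- matrix(0L, Tn, K)
  delta[1, ] <- log(pi0) + logB[1, ]
  if (Tn > 1) for (t in 2:Tn) {
    for (k in seq_len(K)) {
      cand <- delta[t - 1, ] + logA[, k]
      psi[t, k] <- which.max(cand)
      delta[t, k] <- cand[psi[t, k]] + logB[t, k]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Convert decoded HMM states to domains
#'
#' Maximal runs of consecutive bins decoded into bound states are merged
#' into intervals. Runs interrupted by masked bins are not merged across the
#' gap here (see [fill_domain_gaps()] for the explicit gap-filling rule).
#'
#' @param seg An [fit_hmm()] result.
#' @param bins `GRanges` of the track's bins (e.g. `track$bins`).
#' @param bound_states Integer state indices (states ordered by ascending
#'   emission mean) that count as "bound"; default is the highest-mean
#'   state.
#' @return `GRanges` of domains.
#' @export
states_to_domains <- function(seg, bins, bound_states = NULL) {
  if (is.null(bound_states)) bound_states <- seg$n_states
  if (length(bound_states) == 0) stop("bound_states must be non-empty")
  sel <- !is.na(seg$states) & seg$states %in% bound_states
  if (!any(sel)) return(bins[0])
  GenomicRanges::reduce(bins[sel], ignore.strand = TRUE)
}

#' Fill short gaps between domains
#'
#' Consecutive same-chromosome domains separated by a gap strictly shorter
#' than `max_gap` are merged; a gap of exactly `max_gap` is left open.
#'
#' @param domains Sorted, non-overlapping `GRanges`.
#' @param max_gap Maximum unfilled gap in bp (default 900).
#' @return `GRanges` with gaps filled.
#' @export
fill_domain_gaps <- function(domains, max_gap = 900) {
  if (length(domains) == 0) return(domains)
  GenomicRanges::reduce(domains, min.gapwidth = max_gap,
                        ignore.strand = TRUE)
}
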