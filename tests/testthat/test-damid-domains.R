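make_counts <- function(lay, bs, counts) binned_track(lay, bs, counts)

test_that("normalization reproduces hand-computed RPM ratios", {
  lay <- tiny_layout(1200)  # 4 bins of 300
  ## fusion bin1 = 3 of total 30; dam bin1 = 1 of total 10 -> equal RPM
  fusion <- make_counts(lay, 300, c(3, 9, 9, 9))
  dam <- make_counts(lay, 300, c(1, 3, 3, 3))
  res <- normalize_damid(fusion, dam, pseudocount = 0)
  expect_equal(res$log2_ratio$values[1], 0)

  ## fusion RPM exactly twice dam RPM -> +1
  fusion2 <- make_counts(lay, 300, c(2, 1, 1, 1))
  dam2 <- make_counts(lay, 300, c(1, 1, 1.5, 1.5))
  res2 <- normalize_damid(fusion2, dam2, pseudocount = 0)
  expect_equal(res2$log2_ratio$values[1], 1)

  ## zero dam count with zero pseudocount -> masked
  dam3 <- make_counts(lay, 300, c(0, 3, 3, 4))
  res3 <- normalize_damid(fusion, dam3, pseudocount = 0)
  expect_false(res3$log2_ratio$mask[1])
  expect_error(normalize_damid(fusion, make_counts(lay, 300, rep(0, 4))),
               "all-zero")
})

test_that("normalization is invariant to uniform count scaling (RPM)", {
  lay <- tiny_layout(3000)
  set.seed(5)
  f <- make_counts(lay, 300, rpois(10, 50))
  d <- make_counts(lay, 300, rpois(10, 50) + 1)
  r1 <- normalize_damid(f, d, pseudocount = 0)$log2_ratio$values
  f10 <- make_counts(lay, 300, f$values * 10)
  r2 <- normalize_damid(f10, d, pseudocount = 0)$log2_ratio$values
  expect_equal(r1, r2)
})

test_that("replicates are summed and low correlation warns", {
  lay <- tiny_layout(3000)
  set.seed(6)
  f1 <- make_counts(lay, 300, rpois(10, 100))
  f2 <- make_counts(lay, 300, rpois(10, 100))
  d <- make_counts(lay, 300, rpois(10, 100))
  merged <- suppressWarnings(normalize_damid(list(f1, f2), d,
                                             pseudocount = 0))
  byhand <- normalize_damid(make_counts(lay, 300, f1$values + f2$values),
                            d, pseudocount = 0)
  expect_equal(merged$log2_ratio$values, byhand$log2_ratio$values)

  anti <- make_counts(lay, 300, rev(f1$values))
  expect_warning(normalize_damid(list(f1, anti), d, pseudocount = 0),
                 "replicate correlation")
})

test_that("two-state HMM recovers planted levels with high accuracy", {
  set.seed(11)
  n <- 5000
  lay <- genome_layout("c1", n * 300)
  truth <- rep(rep(c(0L, 1L), 25), each = 100)
  x <- rnorm(n, ifelse(truth == 1L, 1.2, -1.2), 0.4)
  fit <- fit_hmm(binned_track(lay, 300, x), n_states = 2)
  expect_true(fit$means[1] < fit$means[2])  # canonical order
  expect_true(all(rowSums(fit$transition) - 1 < 1e-9))
  acc <- mean((fit$states - 1L) == truth)
  expect_gte(acc, 0.95)

  ## same input -> identical segmentation (deterministic fit)
  fit2 <- fit_hmm(binned_track(lay, 300, x), n_states = 2)
  expect_identical(fit$states, fit2$states)
})

test_that("three-state HMM recovers the top level", {
  set.seed(12)
  n <- 3000
  lay <- genome_layout("c1", n * 300)
  lv <- rep(rep(c(1L, 2L, 3L), 10), each = 100)
  x <- rnorm(n, c(-1, 0, 1.5)[lv], 0.3)
  fit <- fit_hmm(binned_track(lay, 300, x), n_states = 3)
  top_truth <- lv == 3L
  top_called <- fit$states == 3L
  recall <- sum(top_truth & top_called) / sum(top_truth)
  expect_gte(recall, 0.90)
})

test_that("HMM handles constant tracks and masked gaps", {
  lay <- genome_layout("c1", 100 * 300)
  const <- binned_track(lay, 300, rep(1.5, 100))
  fit <- fit_hmm(const, n_states = 2)
  expect_true(fit$var_floored)
  expect_length(unique(fit$states[!is.na(fit$states)]), 1)

  ## masked bins stay undecoded and split the chain
  x <- rep(c(-1, 1), each = 50) + rnorm(100, 0, 0.2)
  x[40:45] <- NA
  fitm <- fit_hmm(binned_track(lay, 300, x), n_states = 2)
  expect_true(all(is.na(fitm$states[40:45])))
  expect_false(anyNA(fitm$states[1:39]))
})

test_that("state runs become domains exactly as the RLE oracle says", {
  lay <- genome_layout("c1", 6 * 300)
  bins <- bin_genome(lay, 300)
  seg <- structure(list(n_states = 2L,
                        states = c(1L, 1L, 2L, 2L, 1L, 1L)),
                   class = "hmm_fit")
  dom <- states_to_domains(seg, bins)
  expect_equal(GenomicRanges::start(dom) - 1, 600)
  expect_equal(GenomicRanges::end(dom), 1200)

  seg0 <- structure(list(n_states = 2L, states = rep(1L, 6)),
                    class = "hmm_fit")
  expect_length(states_to_domains(seg0, bins), 0)
  expect_error(states_to_domains(seg, bins, integer(0)), "non-empty")

  set.seed(13)
  lay2 <- genome_layout(c("a", "b"), c(50 * 300, 50 * 300))
  bins2 <- bin_genome(lay2, 300)
  for (i in 1:5) {
    st <- sample(1:2, 100, replace = TRUE)
    segr <- structure(list(n_states = 2L, states = st), class = "hmm_fit")
    got <- states_to_domains(segr, bins2)
    ## oracle: RLE per chromosome (bins 1-50 on a, 51-100 on b)
    want <- c(rle_domains(st[1:50] == 2L, bins2[1:50]),
              rle_domains(st[51:100] == 2L, bins2[51:100]))
    expect_equal(GenomicRanges::start(got), GenomicRanges::start(want))
    expect_equal(GenomicRanges::end(got), GenomicRanges::end(want))
  }
})

test_that("gap filling merges strictly below the threshold only", {
  lay <- tiny_layout(10000)
  d <- bp_interval(c("chrT", "chrT"), c(0, 1600), c(1000, 2000),
                   layout = lay)                     # gap 600
  expect_length(fill_domain_gaps(d, 900), 1)
  d2 <- bp_interval(c("chrT", "chrT"), c(0, 1900), c(1000, 2300),
                    layout = lay)                    # gap exactly 900
  expect_length(fill_domain_gaps(d2, 900), 2)
  expect_length(fill_domain_gaps(d2[0], 900), 0)
})

test_that("planted LADs are recovered with base-level F1 >= 0.9", {
  p <- damid_sim_params(signal = "lam", seed = 101)
  sim <- simulate_damid_counts(p)
  norm <- normalize_damid(sim$fusion, sim$dam)
  fit <- fit_hmm(norm$log2_ratio, n_states = 2)
  lads <- fill_domain_gaps(states_to_domains(fit, norm$log2_ratio$bins))
  f1 <- perichrom:::domain_f1(lads, sim$truth$lads, p$layout, p$bin_size)
  expect_gte(f1, 0.9)
})
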