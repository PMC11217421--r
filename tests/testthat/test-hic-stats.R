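test_that("contact matrix validates shape, symmetry, sign", {
  expect_error(contact_matrix("c", 2000, matrix(1, 2, 3)), "square")
  M <- matrix(c(1, 2, 3, 4), 2)
  expect_error(contact_matrix("c", 2000, M), "symmetric")
  expect_error(contact_matrix("c", 2000, -diag(2)), "non-negative")
  expect_error(contact_matrix("c", 0, diag(2)), "bin_size")
})

test_that("COO contact lists round-trip", {
  set.seed(90)
  cm <- contact_matrix("chrH", 2000, random_count_matrix(15, 3))
  f <- tempfile(fileext = ".tsv")
  write_contacts_coo(cm, f)
  back <- read_contacts_coo(f)
  expect_equal(back$mat, cm$mat)
  expect_equal(back$chrom, "chrH")
  expect_equal(back$bin_size, 2000L)
  writeLines("1\t2\t3", f2 <- tempfile())
  expect_error(read_contacts_coo(f2), "header")
})

test_that("short-range filter zeroes by midpoint separation", {
  set.seed(91)
  cm <- contact_matrix("c", 2000, random_count_matrix(10))
  out <- remove_short_range(cm, 1000)
  expect_true(all(diag(out$mat) == 0))
  off <- out$mat[cbind(1:9, 2:10)]
  expect_equal(off, cm$mat[cbind(1:9, 2:10)])  # 2-kb off-diagonal kept

  cm500 <- contact_matrix("c", 500, cm$mat)
  out500 <- remove_short_range(cm500, 1000)
  expect_true(all(out500$mat[cbind(1:9, 2:10)] == 0))   # 500 bp < 1 kb
  expect_equal(out500$mat[cbind(1:8, 3:10)],
               cm$mat[cbind(1:8, 3:10)])                 # 1 kb kept
  expect_equal(remove_short_range(cm, 0)$mat, cm$mat)
})

test_that("downsampling thins toward the target and is seeded", {
  set.seed(92)
  cm <- contact_matrix("c", 2000, random_count_matrix(40, 30))
  tot <- sum(cm$mat[upper.tri(cm$mat, diag = TRUE)])
  target <- round(tot / 2)
  d1 <- downsample_contacts(cm, target, seed = 7)
  d2 <- downsample_contacts(cm, target, seed = 7)
  expect_identical(d1$mat, d2$mat)
  got <- sum(d1$mat[upper.tri(d1$mat, diag = TRUE)])
  sd_bound <- 3 * sqrt(tot * 0.5 * 0.5)
  expect_lt(abs(got - target), sd_bound)
  expect_identical(d1$mat, t(d1$mat))
  same <- downsample_contacts(cm, tot, seed = 1)
  expect_equal(same$mat, cm$mat)
  expect_error(downsample_contacts(cm, tot + 1), "exceeds")
})

test_that("iterative correction equalizes row sums", {
  set.seed(93)
  cm <- contact_matrix("c", 2000, random_count_matrix(100, 20))
  bal <- iterative_correction(cm)
  rs <- rowSums(bal$mat[bal$valid, bal$valid])
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-6)
  expect_true(attr(bal, "converged"))
  expect_identical(bal$mat, t(bal$mat))

  ## already-balanced matrix is left essentially unchanged
  flat <- matrix(1, 30, 30)
  balf <- iterative_correction(contact_matrix("c", 2000, flat),
                               mask_quantile = 0)
  expect_true(all(abs(balf$mat - 1) < 1e-9))

  ## all-zero row is masked out
  M <- random_count_matrix(30, 10)
  M[5, ] <- 0; M[, 5] <- 0
  balz <- iterative_correction(contact_matrix("c", 2000, M),
                               mask_quantile = 0)
  expect_false(balz$valid[5])
  expect_true(all(is.na(balz$mat[5, ])))
})

test_that("O/E normalizes every diagonal to unit mean", {
  set.seed(94)
  bal <- iterative_correction(contact_matrix("c", 2000,
                                             random_count_matrix(80, 15)))
  oe <- observed_over_expected(bal)
  for (s in 0:30) {
    i <- seq_len(nrow(oe$mat) - s)
    v <- oe$mat[cbind(i, i + s)]
    v <- v[is.finite(v)]
    expect_lt(abs(mean(v) - 1), 1e-12)
  }
  ## uniform matrix -> O/E all ones
  u <- contact_matrix("c", 2000, matrix(4, 20, 20), balanced = TRUE)
  expect_true(all(abs(observed_over_expected(u)$mat - 1) < 1e-12))
  ## synthetic decay c/s recovered by the expected profile
  n <- 60
  sep <- abs(outer(1:n, 1:n, "-")); sep[sep == 0] <- 1
  dec <- contact_matrix("c", 2000, 12 / sep, balanced = TRUE)
  ep <- expected_profile(dec)
  expect_equal(ep[2:20], 12 / (1:19), tolerance = 1e-12)
})

test_that("Armatus preprocessing interpolates, clips and logs", {
  ## all-equal values: clip is identity, ln applied
  flat <- contact_matrix("c", 4000, matrix(3, 10, 10), balanced = TRUE)
  pre <- armatus_preprocess(flat)
  expect_true(all(abs(pre$mat - log(3)) < 1e-12))

  ## single missing cell between 2 and 4 on its diagonal -> 3 before ln
  n <- 8
  M <- matrix(5, n, n)
  M[cbind(1:(n - 2), 3:n)] <- c(2, NA, 4, 3, 3, 3)
  M[cbind(3:n, 1:(n - 2))] <- c(2, NA, 4, 3, 3, 3)
  cm <- contact_matrix("c", 4000, M, balanced = TRUE)
  pre2 <- armatus_preprocess(cm)
  expect_equal(pre2$mat[2, 4], log(3))

  ## heavy outlier clipped to the 99th percentile of finite cells
  set.seed(95)
  B <- random_symmetric(40, function(m) runif(m, 1, 2))
  B[1, 40] <- B[40, 1] <- 1000
  cm3 <- contact_matrix("c", 4000, B, balanced = TRUE)
  pre3 <- armatus_preprocess(cm3)
  q99 <- quantile(B[is.finite(B)], 0.99, names = FALSE)
  expect_equal(max(pre3$mat), log(q99))
})

test_that("TAD dynamic program equals the exhaustive oracle (n <= 12)", {
  set.seed(96)
  for (rep in 1:6) {
    n <- sample(6:12, 1)
    L <- random_symmetric(n)
    cm <- contact_matrix("c", 4000, L, balanced = TRUE, transformed = TRUE)
    for (g in c(0.4, 0.6, 1.0)) {
      tads <- call_tads(cm, g)
      expect_equal(attr(tads, "score"), brute_tad_score(L, g),
                   tolerance = 1e-10)
    }
  }
  expect_error(call_tads(contact_matrix("c", 4000, diag(5),
                                        balanced = TRUE), -1), "gamma")
})

test_that("planted dense blocks are recovered exactly; uniform gives none", {
  n <- 40
  M <- matrix(1, n, n)
  M[5:14, 5:14] <- 3
  M[25:34, 25:34] <- 3
  noise <- random_symmetric(n, function(m) runif(m, -0.01, 0.01))
  cm <- contact_matrix("c", 4000, M + noise - min(noise),
                       balanced = TRUE)
  tads <- call_tads(armatus_preprocess(cm), 1)
  expect_true(any(tads$start_bin == 5 & tads$end_bin == 14))
  expect_true(any(tads$start_bin == 25 & tads$end_bin == 34))

  uni <- contact_matrix("c", 4000, matrix(2, 20, 20), balanced = TRUE)
  expect_equal(nrow(call_tads(armatus_preprocess(uni), 1)), 0)
})

test_that("TAD matching requires identical boundaries", {
  a <- data.frame(start_bin = c(1, 10, 20), end_bin = c(9, 19, 30))
  b <- data.frame(start_bin = c(1, 11, 20), end_bin = c(9, 19, 30))
  m <- match_tads(a, b)
  expect_equal(m$idx_a, c(1, 3))
  expect_equal(m$idx_b, c(1, 3))
  expect_equal(nrow(match_tads(a, a)), 3)
  expect_equal(nrow(match_tads(a[0, ], b)), 0)
})

test_that("ACF matches hand means and identical maps give zero log2FC", {
  n <- 10
  M <- matrix(1, n, n)
  M[1, 2] <- M[2, 1] <- 1
  M[1, 3] <- M[3, 1] <- 2
  M[2, 3] <- M[3, 2] <- 3
  oe <- contact_matrix("c", 4000, M, balanced = TRUE)
  expect_equal(tad_acf(oe, 1, 3), 2)          # mean(1, 2, 3)
  u <- contact_matrix("c", 4000, matrix(7, n, n), balanced = TRUE)
  expect_equal(tad_acf(u, 2, 6), 7)
  expect_warning(expect_true(is.na(tad_acf(oe, 4, 4))), "one-bin")

  tads <- data.frame(start_bin = c(1, 5), end_bin = c(4, 9))
  fc <- acf_log2fc(oe, oe, tads)
  expect_true(all(fc$log2fc == 0))
})

test_that("Jacc grouping matches closed forms and is antisymmetric", {
  lay <- genome_layout("c", 40 * 4000)
  tads <- data.frame(start_bin = c(1, 11, 21, 31),
                     end_bin = c(10, 20, 30, 40),
                     start = c(0, 10, 20, 30) * 4000,
                     end = c(10, 20, 30, 40) * 4000)
  ## (X, Y) = (1,0), (0,1), (0.5,0.5), (0,0)
  lads <- bp_interval(c("c", "c"), c(0, 80000), c(40000, 100000),
                      layout = lay)
  active <- bp_interval(c("c", "c"), c(40000, 100000), c(80000, 120000),
                        layout = lay)
  g <- jaccard_group(tads, lads, active, lay, chrom = "c")
  expect_equal(g$jacc, c(1, -1, 0, 0))
  expect_equal(g$group, c("C", "A", "B", "B"))
  ## swapping X and Y negates Jacc and swaps A/C
  g2 <- jaccard_group(tads, active, lads, lay, chrom = "c")
  expect_equal(g2$jacc, -g$jacc)
  expect_equal(g2$group, c("A", "C", "B", "B"))
})

test_that("ISm equals the 16-cell oracle exactly on random matrices", {
  set.seed(97)
  for (rep in 1:100) {
    M <- random_symmetric(30, function(m) runif(m))
    oe <- contact_matrix("c", 2000, M, balanced = TRUE)
    ism <- ism_profile(oe)
    for (i in c(5, 9, 15, 22, 26))
      expect_identical(ism[i], ism_oracle(M, i))
    expect_true(all(is.na(ism[c(1:4, 27:30)])))
  }
  u <- contact_matrix("c", 2000, matrix(1, 20, 20), balanced = TRUE)
  expect_true(all(ism_profile(u)[5:16] == 1))
  expect_error(ism_profile(contact_matrix("c", 4000, diag(20),
                                          balanced = TRUE)),
               "2000")
})

test_that("ISm anchor curve averages and interpolates", {
  ism <- rep(2, 100)
  flat <- averaged_ism_around(ism, 2000, c(30, 60), 5)
  expect_true(all(flat$mean == 2))
  expect_equal(flat$position, seq(-10000, 10000, 2000))

  ## single gap interpolated to the midpoint of its neighbors
  ism2 <- rep(1, 100); ism2[30] <- NA; ism2[29] <- 0; ism2[31] <- 4
  curve <- averaged_ism_around(ism2, 2000, 30, 3)
  expect_equal(curve$mean[4], 2)   # (0 + 4) / 2

  ## anchor boost: ISm peaks at the center
  p <- hic_sim_params(anchors = c(4e5, 8e5, 1.2e6, 1.6e6),
                      anchor_boost = 3, compartment_blocks = NA,
                      seed = 98)
  sim <- simulate_hic(p)
  oe <- observed_over_expected(iterative_correction(
    remove_short_range(sim$cm)))
  ism3 <- ism_profile(oe)
  curve3 <- averaged_ism_around(ism3, 2000, sim$truth$anchor_bins, 10)
  center <- which(curve3$position == 0)
  expect_gt(curve3$mean[center],
            mean(curve3$mean[abs(curve3$position) >= 16000]))
  expect_error(averaged_ism_around(ism, 2000, 1000, 5), "no anchors")
})

test_that("compartment PC1 recovers a planted checkerboard", {
  p <- hic_sim_params(tad_boundaries = numeric(0), anchors = numeric(0),
                      seed = 99)
  sim <- simulate_hic(p)
  cm10 <- rebin_contacts(remove_short_range(sim$cm), 5)
  oe <- observed_over_expected(iterative_correction(cm10))
  comp <- sim$truth$compartments
  ori <- perichrom:::comp_orientation(comp, 5, nrow(oe$mat))
  pc1 <- compartment_pc1(oe, ori)
  ok <- is.finite(pc1)
  agree <- mean((pc1[ok] > 0) == (ori[ok] > 0.5))
  expect_gte(agree, 0.95)
  ## orientation contract
  expect_gte(cor(pc1, ori, use = "pairwise.complete.obs"), 0)
  ## degenerate matrix flagged
  u <- contact_matrix("c", 10000, matrix(1, 30, 30), balanced = TRUE)
  pc_u <- compartment_pc1(u, runif(30))
  expect_true(attr(pc_u, "degenerate"))
})

test_that("saddle grid is unit for uniform maps and orders corners", {
  u <- contact_matrix("c", 10000, matrix(1, 200, 200), balanced = TRUE)
  set.seed(100)
  pc <- rnorm(200)
  sad <- saddle(u, pc, n_quantiles = 20, trim = 0.01)
  expect_true(all(abs(sad$grid - 1) < 1e-12))
  d <- saddle_difference_summary(sad, sad, k = 5)
  expect_true(all(abs(c(d$AA, d$BB, d$AB)) < 1e-12))
  expect_true(all(d$summary$p_wilcoxon == 1))

  ## checkerboard: same-compartment corners beat the off-diagonal blocks
  p <- hic_sim_params(tad_boundaries = numeric(0), anchors = numeric(0),
                      seed = 101)
  sim <- simulate_hic(p)
  cm10 <- rebin_contacts(remove_short_range(sim$cm), 5)
  oe <- observed_over_expected(iterative_correction(cm10))
  ori <- perichrom:::comp_orientation(sim$truth$compartments, 5,
                                      nrow(oe$mat))
  pc1 <- compartment_pc1(oe, ori)
  sad2 <- saddle(oe, pc1, n_quantiles = 20, trim = 0.01)
  k <- 5; nq <- 20
  aa <- mean(sad2$grid[(nq - k + 1):nq, (nq - k + 1):nq], na.rm = TRUE)
  bb <- mean(sad2$grid[1:k, 1:k], na.rm = TRUE)
  ab <- mean(c(sad2$grid[1:k, (nq - k + 1):nq],
               sad2$grid[(nq - k + 1):nq, 1:k]), na.rm = TRUE)
  expect_gt(aa, ab)
  expect_gt(bb, ab)
})

test_that("pileups average windows and flag the planted anchor cross", {
  u <- contact_matrix("c", 2000, matrix(1, 50, 50), balanced = TRUE)
  pu <- pileup_oe(u, c(20, 30), 5)
  expect_true(all(pu$grid == 1))
  expect_equal(pu$n_anchors, 2)

  ## single anchor returns the window itself
  set.seed(102)
  M <- random_symmetric(50, function(m) runif(m))
  oe <- contact_matrix("c", 2000, M, balanced = TRUE)
  pu1 <- pileup_oe(oe, 25, 4)
  expect_equal(pu1$grid, M[21:29, 21:29])

  ## anchor-boost simulation enriches the central cross over corners
  p <- hic_sim_params(anchors = c(4e5, 8e5, 1.2e6, 1.6e6),
                      anchor_boost = 3, compartment_blocks = NA,
                      seed = 103)
  sim <- simulate_hic(p)
  oeb <- observed_over_expected(iterative_correction(
    remove_short_range(sim$cm)))
  pub <- pileup_oe(oeb, sim$truth$anchor_bins, 8)
  c0 <- 9  # center index
  cross <- mean(pub$grid[(c0 - 4):(c0 - 1), (c0 + 1):(c0 + 4)])
  ## far off-diagonal corner (the matrix diagonal inside the window is
  ## undefined after short-range filtering, so stay off it)
  corner <- mean(pub$grid[1:4, 14:17])
  expect_gt(cross, corner)
  expect_error(pileup_oe(u, 1, 10), "no anchors")
})

test_that("rebinning aggregates counts preserving totals", {
  set.seed(104)
  cm <- contact_matrix("c", 2000, random_count_matrix(20))
  r2 <- rebin_contacts(cm, 2)
  expect_equal(sum(r2$mat), sum(cm$mat))
  expect_equal(nrow(r2$mat), 10)
  expect_equal(r2$bin_size, 4000L)
  expect_equal(r2$mat[1, 1], sum(cm$mat[1:2, 1:2]))
  expect_equal(r2$mat[1, 2], sum(cm$mat[1:2, 3:4]))
})
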