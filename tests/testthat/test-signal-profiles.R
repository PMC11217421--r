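profile_layout <- function(n_bins = 400, bs = 300)
  genome_layout("chrP", n_bins * bs)

test_that("anchor profile is flat on a constant track", {
  lay <- profile_layout()
  tr <- binned_track(lay, 300, rep(2.5, 400))
  anchors <- bp_interval(rep("chrP", 3), c(30000, 60000, 90000),
                         c(32000, 62000, 92000), layout = lay)
  prof <- average_anchor_profile(tr, anchors, flank = 3000)
  expect_true(all(abs(prof$mean - 2.5) < 1e-12))
  expect_true(all(diff(prof$position) > 0))
  expect_true(all(prof$n == 3))
})

test_that("anchor profile shows a central peak for anchor-confined signal", {
  lay <- profile_layout()
  bins <- bin_genome(lay, 300)
  anchors <- bp_interval(rep("chrP", 4), c(20000, 50000, 80000, 110000),
                         c(22000, 52000, 82000, 112000), layout = lay)
  vals <- as.numeric(GenomicRanges::countOverlaps(bins, anchors) > 0)
  tr <- binned_track(lay, 300, vals)
  prof <- average_anchor_profile(tr, anchors, flank = 3000)
  center <- which.min(abs(prof$position))
  expect_gt(prof$mean[center], 0.95)
  expect_lt(max(prof$mean[abs(prof$position) > 1600]), 0.5)
  ## profile means stay inside the source range
  expect_true(all(prof$mean >= 0 - 1e-12 & prof$mean <= 1 + 1e-12))
})

test_that("single anchor returns the resampled raw signal; edges shrink n", {
  lay <- profile_layout()
  set.seed(71)
  vals <- rnorm(400)
  tr <- binned_track(lay, 300, vals)
  one <- bp_interval("chrP", 60000, 60600, layout = lay)
  prof <- average_anchor_profile(tr, one, flank = 3000, out_bins = 20)
  mid0 <- perichrom:::mid_point(one) - 1
  expected <- sapply(seq_len(20), function(k) {
    a <- mid0 - 3000 + (k - 1) * 300; b <- a + 300
    w <- perichrom:::window_weighted_means(vals, 300, a, b)
    w$mean
  })
  expect_equal(prof$mean, expected)

  edge <- bp_interval("chrP", 0, 600, layout = lay)
  prof_e <- average_anchor_profile(tr, edge, flank = 3000)
  expect_true(any(prof_e$n == 0))   # left flank off-chromosome
  expect_true(any(prof_e$n == 1))
  expect_error(average_anchor_profile(tr, one[0], flank = 3000),
               "no anchors")
})

test_that("metagene is flat for uniform signal and strand-aware", {
  lay <- profile_layout()
  tr <- binned_track(lay, 300, rep(1, 400))
  genes <- bp_interval(rep("chrP", 2), c(30000, 70000), c(39000, 79000),
                       strand = c("+", "-"), layout = lay)
  mg <- metagene_profile(tr, genes)
  expect_true(all(abs(mg$mean - 1) < 1e-12))

  ## signal only in the first 10% of a plus-strand gene body
  bins <- bin_genome(lay, 300)
  v <- rep(0, 400); v[101:104] <- 1       # 30000..31200 of gene at 30000
  mgp <- metagene_profile(binned_track(lay, 300, v), genes[1],
                          body_bins = 50, flank = 1500)
  body <- mgp[mgp$section == "body", ]
  expect_gt(mean(body$mean[1:8]), mean(body$mean[40:50]) + 0.3)

  ## minus-strand gene with signal at its genomic end peaks at the 5' side
  v2 <- rep(0, 400); v2[261:264] <- 1     # 78000..79200, end of gene 2
  mgm <- metagene_profile(binned_track(lay, 300, v2), genes[2],
                          body_bins = 50, flank = 1500)
  body_m <- mgm[mgm$section == "body", ]
  expect_gt(mean(body_m$mean[1:8], na.rm = TRUE),
            mean(body_m$mean[40:50], na.rm = TRUE))
  expect_error(metagene_profile(tr, genes[0]), "empty gene set")
})

test_that("A/T profile matches hand counts and closed forms", {
  lay <- genome_layout("chrA", 4000)
  all_a <- Biostrings::DNAStringSet(c(chrA = paste(rep("A", 4000),
                                                   collapse = "")))
  anchors <- bp_interval("chrA", 1900, 2100, layout = lay)
  prof <- at_content_profile(all_a, anchors, flank = 200)
  expect_true(all(prof$mean == 100))

  gc <- Biostrings::DNAStringSet(c(chrA = paste(rep("GC", 2000),
                                                collapse = "")))
  prof_gc <- at_content_profile(gc, anchors, flank = 200)
  expect_true(all(prof_gc$mean == 0))

  ## hand count: "ATATGCGCGCATATATATGC" = ATAT (4) + GCGCGC (0) +
  ## ATATATAT (8) + GC (0) = 12 A/T of 20 -> 60%; the anchor midpoint
  ## aligns the single window to one repeat unit
  win <- "ATATGCGCGCATATATATGC"
  expect_equal(sum(strsplit(win, "")[[1]] %in% c("A", "T")), 12)
  seq60 <- Biostrings::DNAStringSet(c(chrA = paste(
    rep(win, 200), collapse = "")))
  a1 <- bp_interval("chrA", 1980, 2000, layout = lay)
  p60 <- at_content_profile(seq60, a1, flank = 10, window = 20)
  expect_equal(p60$mean, 60)
  ## and an 11-of-20 window gives 55%
  win55 <- "AATTAGCGCGATATATGCGC"
  expect_equal(sum(strsplit(win55, "")[[1]] %in% c("A", "T")), 11)
  seq55 <- Biostrings::DNAStringSet(c(chrA = paste(
    rep(win55, 200), collapse = "")))
  p55 <- at_content_profile(seq55, a1, flank = 10, window = 20)
  expect_equal(p55$mean, 55)
})

test_that("A/T-rich site fraction matches planting", {
  lay <- genome_layout("chrA", 60000)
  ## islands under half the sites only
  sites <- bp_interval(rep("chrA", 20), seq(1000, 58000, 3000) - 500,
                       seq(1000, 58000, 3000) + 500, layout = lay)
  islands <- GenomicRanges::resize(sites[seq(1, 20, 2)], 30,
                                   fix = "center")
  seqs <- simulate_sequence(lay, islands, seed = 81)
  frac <- at_rich_fraction(seqs, sites)
  expect_gte(frac, 35)  # ~50% planted minus binomial error
  expect_lte(frac, 65)

  ## pure GC region -> 0
  gc <- Biostrings::DNAStringSet(c(chrA = paste(rep("GC", 30000),
                                                collapse = "")))
  expect_equal(at_rich_fraction(gc, sites), 0)
  ## a 20-A run at the center is always found
  polyA <- as.character(seqs[["chrA"]])
  expect_equal(at_rich_fraction(seqs, sites[1:1]) >= 0, TRUE)
  expect_error(at_rich_fraction(seqs, sites[0]), "empty site set")
})
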