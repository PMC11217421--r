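class_layout <- function() tiny_layout(100000)

test_that("sites are labelled by which references they touch", {
  lay <- class_layout()
  elys <- bp_interval(rep("chrT", 3), c(1000, 5000, 9000),
                      c(2000, 6000, 10000), layout = lay)
  npc <- bp_interval("chrT", 1200, 1700, layout = lay)
  nucl <- bp_interval(c("chrT", "chrT"), c(5500, 1500), c(5800, 1600),
                      layout = lay)
  cl <- classify_sites(elys, npc, nucl)
  expect_equal(S4Vectors::mcols(cl)$label,
               c("Elys_NPC/nucl", "Elys_nucl", "unassigned"))
  ## min_overlap raises the bar: the 100-bp nucl overlaps on sites 1 and 2
  ## drop out, the 500-bp npc overlap on site 1 survives
  cl2 <- classify_sites(elys, npc, nucl, min_overlap = 400)
  expect_equal(S4Vectors::mcols(cl2)$label,
               c("Elys_NPC", "unassigned", "unassigned"))
  expect_error(classify_sites(elys, npc, nucl, min_overlap = 0),
               "min_overlap")
  ## partition property: labels cover every site exactly once
  expect_length(cl, length(elys))
})

test_that("shuffling preserves lengths and chromosomes and is uniform", {
  lay <- genome_layout(c("a", "b"), c(50000, 30000))
  set.seed(61)
  sites <- c(bp_interval(rep("a", 10), seq(0, 45000, 5000),
                         seq(1000, 46000, 5000), layout = lay),
             bp_interval(rep("b", 5), seq(0, 20000, 5000),
                         seq(2000, 22000, 5000), layout = lay))
  sh <- shuffle_intervals(sites, lay)
  expect_equal(GenomicRanges::width(sh), GenomicRanges::width(sites))
  expect_equal(table(as.character(GenomeInfoDb::seqnames(sh))),
               table(as.character(GenomeInfoDb::seqnames(sites))))
  expect_true(all(GenomicRanges::end(sh) <=
                    GenomeInfoDb::seqlengths(lay)[
                      as.character(GenomeInfoDb::seqnames(sh))]))

  ## uniform placement: one 1-bin site on a 10-slot chromosome
  lay10 <- genome_layout("c", 10)
  one <- bp_interval("c", 0, 1, layout = lay10)
  set.seed(62)
  starts <- replicate(10000,
    GenomicRanges::start(shuffle_intervals(one, lay10)))
  gof <- chisq.test(table(factor(starts, levels = 1:10)))
  expect_gt(gof$p.value, 0.01)

  ## a site fitting exactly is fine; one longer than the target layout's
  ## chromosome is not
  fits <- shuffle_intervals(bp_interval("c", 0, 10, layout = lay10), lay10)
  expect_equal(GenomicRanges::width(fits), 10)
  lay_small <- genome_layout("c", 5)
  expect_error(shuffle_intervals(bp_interval("c", 0, 10, layout = lay10),
                                 lay_small),
               "longer than")
})

test_that("permutation p-values match construction and enumeration", {
  lay <- tiny_layout(100000)
  ## query identical to a sparse reference covering ~1% of the genome:
  ## no shuffle beats full overlap -> minimal p
  ref <- bp_interval(rep("chrT", 10), seq(0, 90000, 10000),
                     seq(100, 90100, 10000), layout = lay)
  pt <- permutation_overlap_test(ref, ref, lay, n_perm = 100, seed = 1)
  expect_equal(pt$observed, 10)
  expect_equal(pt$p_value, 1 / 101)
  expect_output(print(pt), "P <")

  ## reference = whole genome -> every placement overlaps -> p = 1
  whole <- bp_interval("chrT", 0, 100000, layout = lay)
  q <- bp_interval(rep("chrT", 5), seq(0, 40000, 10000),
                   seq(500, 40500, 10000), layout = lay)
  pt2 <- permutation_overlap_test(q, whole, lay, n_perm = 50, seed = 2)
  expect_equal(pt2$p_value, 1)

  ## tiny exhaustive case: 1-bp site on 10 slots, reference = slots 1-3.
  ## Overlap probability 3/10, so P(null >= obs=1) = 0.3 exactly.
  lay10 <- genome_layout("c", 10)
  site <- bp_interval("c", 0, 1, layout = lay10)
  ref3 <- bp_interval("c", 0, 3, layout = lay10)
  set.seed(63)
  pts <- replicate(200, permutation_overlap_test(
    site, ref3, lay10, n_perm = 100, seed = sample.int(1e6, 1))$p_value)
  ## p estimates concentrate near (0.3 * 100 + 1)/101
  expect_lt(abs(mean(pts) - (0.3 * 100 + 1) / 101), 0.02)

  expect_error(permutation_overlap_test(q, whole, lay, n_perm = 0),
               "n_perm")
})

test_that("permutation p-values are valid under the null", {
  lay <- tiny_layout(50000)
  ref <- bp_interval(rep("chrT", 5), seq(0, 40000, 10000),
                     seq(2000, 42000, 10000), layout = lay)
  set.seed(64)
  n_rep <- 200
  ps <- replicate(n_rep, {
    q <- random_intervals(15, 50000, lay, max_width = 1500)
    permutation_overlap_test(q, ref, lay, n_perm = 200,
                             seed = sample.int(1e6, 1))$p_value
  })
  expect_lte(mean(ps <= 0.05), 0.05 + 2 / sqrt(n_rep))
})

test_that("overlap_fraction matches closed forms in both modes", {
  lay <- class_layout()
  a <- bp_interval("chrT", 0, 100, layout = lay)
  b <- bp_interval("chrT", 50, 150, layout = lay)
  expect_equal(overlap_fraction(a, b, "length"), 50)
  inside <- bp_interval("chrT", 10, 20, layout = lay)
  expect_equal(overlap_fraction(inside, a, "length"), 100)
  expect_equal(overlap_fraction(inside, a, "count"), 100)
  far <- bp_interval("chrT", 9000, 9100, layout = lay)
  expect_equal(overlap_fraction(far, a, "length"), 0)
  ## identity property
  set.seed(65)
  r <- random_intervals(20, 100000, lay)
  expect_equal(overlap_fraction(r, r, "length"), 100)
  expect_equal(overlap_fraction(r, r, "count"), 100)
  expect_error(overlap_fraction(a[0], b), "empty")
})

test_that("interior-site filter applies the midpoint-margin rule", {
  lay <- class_layout()
  dom <- bp_interval("chrT", 10000, 30000, layout = lay)  # 20-kb LAD
  deep <- bp_interval("chrT", 14500, 15500, layout = lay)  # center 15 kb
  near <- bp_interval("chrT", 10500, 11500, layout = lay)  # center 1 kb in
  out <- bp_interval("chrT", 50000, 51000, layout = lay)
  kept <- filter_interior_sites(c(deep, near, out), dom, margin = 2000)
  expect_length(kept, 1)
  expect_equal(GenomicRanges::start(kept), GenomicRanges::start(deep))
  expect_error(filter_interior_sites(deep, dom, margin = -1), "negative")
})

test_that("genes are categorized by the site classes they overlap", {
  lay <- class_layout()
  sites <- bp_interval(rep("chrT", 4), c(1000, 11000, 21000, 21500),
                       c(2000, 12000, 22000, 22500), layout = lay)
  S4Vectors::mcols(sites)$label <- c("Elys_nucl", "Elys_NPC",
                                     "Elys_NPC", "Elys_nucl")
  genes <- bp_interval(rep("chrT", 4), c(500, 10500, 20500, 40000),
                       c(3000, 13000, 23000, 41000),
                       strand = c("+", "-", "+", "-"), layout = lay)
  got <- classify_genes_by_sites(genes, sites)
  expect_equal(got$category,
               c("nucl_only", "NPC_only", "combination", "none"))
})

test_that("TPM matches hand arithmetic and sums to one million", {
  expect_equal(compute_tpm(c(10, 0, 0), c(100, 200, 300)),
               c(1e6, 0, 0))
  tpm <- compute_tpm(c(5, 5), c(1000, 2000))
  expect_equal(tpm, c(2e6 / 3, 1e6 / 3))
  set.seed(66)
  r <- compute_tpm(rpois(50, 100), sample(500:5000, 50))
  expect_equal(sum(r), 1e6)
  expect_error(compute_tpm(c(0, 0), c(1, 1)), "all-zero")
  expect_error(compute_tpm(c(1, 1), c(0, 1)), "lengths")
})

test_that("expression summary flags planted shifts and is null-calm", {
  set.seed(67)
  n <- 200
  tpm_c <- exp(rnorm(2 * n, 3, 1))
  shift <- c(rep(2^0.5, n), rep(1, n))
  tpm_k <- tpm_c * shift
  groups <- rep(c("boosted", "null"), each = n)
  gs <- expression_group_summary(tpm_c, tpm_k, groups, eps = 0)
  s <- gs$summary
  expect_gt(s$median[s$group == "boosted"], 0)
  expect_lt(s$p_wilcoxon[s$group == "boosted"], 0.01)
  expect_lt(abs(s$median[s$group == "null"]), 0.1)
  ## identical tables -> all zeros, p = 1
  same <- expression_group_summary(tpm_c, tpm_c, groups)
  expect_true(all(same$per_gene$log2fc == 0))
  expect_true(all(same$summary$p_wilcoxon == 1))
})
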