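#' Classify binding sites by overlap with NPC / nucleoplasmic references
#'
#' Each site is labelled by which reference set(s) it shares at least
#' `min_overlap` bases with: only the NPC reference gives `Elys_NPC`, only
#' the nucleoplasmic reference gives `Elys_nucl`, both give
#' `Elys_NPC/nucl`, neither gives `unassigned`.
#'
#' @param elys Sites to classify (`GRanges`).
#' @param npc_ref,nucl_ref Reference interval sets (`GRanges`).
#' @param min_overlap Minimum shared bases to count as an overlap (>= 1).
#' @return `GRanges` equal to `elys` with a `label` metadata column.
#' @export
classify_sites <- function(elys, npc_ref, nucl_ref, min_overlap = 1) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  check_same_layout(elys, npc_ref)
  check_same_layout(elys, nucl_ref)
  npc_bp <- overlap_bp_per_interval(elys, npc_ref)
  nucl_bp <- overlap_bp_per_interval(elys, nucl_ref)
  is_npc <- npc_bp >= min_overlap
  is_nucl <- nucl_bp >= min_overlap
  label <- rep("unassigned", length(elys))
  label[is_npc & !is_nucl] <- "Elys_NPC"
  label[!is_npc & is_nucl] <- "Elys_nucl"
  label[is_npc & is_nucl] <- "Elys_NPC/nucl"
  out <- elys
  S4Vectors::mcols(out)$label <- label
  out
}

overlap_bp_per_interval <- function(a, b) {
  br <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(a, br, ignore.strand = TRUE)
  out <- rep(0, length(a))
  if (length(hits)) {
    w <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(a)[S4Vectors::queryHits(hits)],
      GenomicRanges::ranges(br)[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Randomly reposition intervals on the genome
#'
#' Interval lengths are preserved exactly; each interval is placed uniformly
#' over the valid start positions. Shuffled intervals may overlap each
#' other, mirroring BEDTools-shuffle behaviour without a blacklist.
#'
#' @param sites `GRanges`.
#' @param layout A [genome_layout()].
#' @param preserve_chrom Keep each interval on its own chromosome (default
#'   `TRUE`). When `FALSE`, the target chromosome is drawn with probability
#'   proportional to its number of valid start positions.
#' @return `GRanges` of repositioned intervals.
#' @export
shuffle_intervals <- function(sites, layout, preserve_chrom = TRUE) {
  lens <- layout_lengths(layout)
  w <- GenomicRanges::width(sites)
  if (preserve_chrom) {
    chr <- as.character(GenomeInfoDb::seqnames(sites))
    avail <- lens[chr] - w + 1
    if (any(avail < 1))
      stop("site longer than its chromosome")
    start1 <- 1 + floor(stats::runif(length(sites)) * avail)
  } else {
    chr <- character(length(sites))
    start1 <- integer(length(sites))
    for (i in seq_along(sites)) {
      slots <- pmax(lens - w[i] + 1, 0)
      if (sum(slots) == 0) stop("site longer than any chromosome")
      ci <- sample.int(length(lens), 1, prob = slots)
      chr[i] <- names(lens)[ci]
      start1[i] <- 1 + floor(stats::runif(1) * slots[ci])
    }
  }
  bp_interval(chr, start1 - 1, start1 - 1 + w, layout = layout)
}

#' Permutation test for interval-set overlap
#'
#' The observed statistic is the number of query intervals overlapping the
#' reference by at least one base. The null distribution repositions the
#' query `n_perm` times with [shuffle_intervals()] and recounts. The
#' p-value uses the add-one estimator `(#{null >= observed} + 1) /
#' (n_perm + 1)`, which cannot be zero; the print method reports
#' `P < 1/n_perm` when no permutation reaches the observed count.
#'
#' @param query,reference `GRanges` (non-empty).
#' @param layout A [genome_layout()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the shuffles.
#' @param preserve_chrom Passed to [shuffle_intervals()].
#' @return List of class `perm_test`: `observed`, `null_counts`, `n_perm`,
#'   `p_value`, `seed`.
#' @export
permutation_overlap_test <- function(query, reference, layout,
                                     n_perm = 10000, seed = 0,
                                     preserve_chrom = TRUE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (length(query) == 0 || length(reference) == 0)
    stop("query and reference must be non-empty")
  observed <- sum(GenomicRanges::countOverlaps(
    query, reference, ignore.strand = TRUE) > 0)

  ## Fast path for the permutation loop: reference reduced per chromosome to
  ## sorted disjoint intervals, query placements tested by index arithmetic.
  refr <- GenomicRanges::reduce(reference, ignore.strand = TRUE)
  ref_by_chr <- split(data.frame(
    s = GenomicRanges::start(refr), e = GenomicRanges::end(refr)),
    as.character(GenomeInfoDb::seqnames(refr)))
  lens <- layout_lengths(layout)
  w <- GenomicRanges::width(query)
  chr <- as.character(GenomeInfoDb::seqnames(query))
  avail <- lens[chr] - w + 1
  if (any(avail < 1)) stop("site longer than its chromosome")

  seed <- as.integer(seed)  # force before the RNG snapshot (lazy args)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_counts <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    start1 <- 1 + floor(stats::runif(length(w)) * avail)
    end1 <- start1 + w - 1
    hit <- logical(length(w))
    for (cn in names(ref_by_chr)) {
      sel <- chr == cn
      if (!any(sel)) next
      rs <- ref_by_chr[[cn]]$s; re <- ref_by_chr[[cn]]$e
      ## sorted disjoint reference: the only candidate is the interval with
      ## the greatest start <= query end; overlap iff its end >= query start
      k <- findInterval(end1[sel], rs)
      hit[sel] <- k >= 1 & re[pmax(k, 1)] >= start1[sel]
    }
    null_counts[p] <- sum(hit)
  }
  p_value <- (sum(null_counts >= observed) + 1) / (n_perm + 1)
  structure(list(observed = observed, null_counts = null_counts,
                 n_perm = n_perm, p_value = p_value, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation overlap test:", x$observed, "of observed query",
      "intervals overlap the reference\n")
  cat("  null mean:", round(mean(x$null_counts), 2), " permutations:",
      x$n_perm, "\n")
  if (!any(x$null_counts >= x$observed)) {
    cat("  P <", format(1 / x$n_perm, digits = 3),
        "(no permutation reached the observed count)\n")
  } else {
    cat("  P =", format(x$p_value, digits = 3), "\n")
  }
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Overlap between two interval sets as a percentage
#'
#' @param a,b `GRanges`.
#' @param mode `"length"`: 100 * overlap bases / total bases of `a`;
#'   `"count"`: percentage of `a`'s intervals with >= 1 bp overlap with `b`.
#' @return A percentage in `[0, 100]`.
#' @export
overlap_fraction <- function(a, b, mode = c("length", "count")) {
  mode <- match.arg(mode)
  if (length(a) == 0) stop("empty interval set 'a'")
  if (mode == "length") {
    ov <- sum(GenomicRanges::width(intersect_sets(
      GenomicRanges::reduce(a, ignore.strand = TRUE),
      GenomicRanges::reduce(b, ignore.strand = TRUE))))
    100 * ov / sum(GenomicRanges::width(
      GenomicRanges::reduce(a, ignore.strand = TRUE)))
  } else {
    100 * mean(GenomicRanges::countOverlaps(
      a, b, ignore.strand = TRUE) > 0)
  }
}

#' Keep sites lying deep inside domains
#'
#' A site is kept when its midpoint falls inside a domain and at least
#' `margin` bp away from both domain boundaries (e.g. sites within LADs,
#' +-2 kb from LAD boundaries).
#'
#' @param sites `GRanges`.
#' @param domains Non-overlapping `GRanges`.
#' @param margin Distance from domain boundaries in bp (default 2000).
#' @return The retained subset of `sites`.
#' @export
filter_interior_sites <- function(sites, domains, margin = 2000) {
  if (margin < 0) stop("margin must be non-negative")
  if (length(sites) == 0) return(sites)
  keep_dom <- domains[GenomicRanges::width(domains) > 2 * margin]
  if (length(keep_dom) == 0) return(sites[0])
  core <- GenomicRanges::narrow(keep_dom, start = margin + 1,
                                end = -(margin + 1))
  mids <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(sites),
    IRanges::IRanges(start = mid_point(sites), width = 1))
  sites[GenomicRanges::countOverlaps(mids, core,
                                     ignore.strand = TRUE) > 0]
}

mid_point <- function(gr) {
  (GenomicRanges::start(gr) + GenomicRanges::end(gr)) %/% 2L
}

#' Categorize genes by the classes of sites they overlap
#'
#' A gene overlapping only `Elys_nucl` sites is `nucl_only`, only
#' `Elys_NPC` sites is `NPC_only`, any mixture (including ambivalent
#' `Elys_NPC/nucl` sites) is `combination`, and none is `none`.
#' `unassigned` sites are ignored.
#'
#' @param genes Stranded `GRanges`.
#' @param classes Output of [classify_sites()].
#' @return `data.frame` with one row per gene: `gene_id` (label or index),
#'   `category`.
#' @export
classify_genes_by_sites <- function(genes, classes) {
  lab <- S4Vectors::mcols(classes)$label
  if (is.null(lab)) stop("classes must carry a 'label' column")
  over_npc <- GenomicRanges::countOverlaps(
    genes, classes[lab == "Elys_NPC"], ignore.strand = TRUE) > 0
  over_nucl <- GenomicRanges::countOverlaps(
    genes, classes[lab == "Elys_nucl"], ignore.strand = TRUE) > 0
  over_both <- GenomicRanges::countOverlaps(
    genes, classes[lab == "Elys_NPC/nucl"], ignore.strand = TRUE) > 0
  category <- rep("none", length(genes))
  category[over_nucl & !over_npc & !over_both] <- "nucl_only"
  category[over_npc & !over_nucl & !over_both] <- "NPC_only"
  category[over_both | (over_npc & over_nucl)] <- "combination"
  ids <- S4Vectors::mcols(genes)$label
  if (is.null(ids)) ids <- paste0("gene_", seq_along(genes))
  data.frame(gene_id = ids, category = category,
             stringsAsFactors = FALSE)
}

#' Convert gene counts to transcripts per million
#'
#' `TPM_g = 1e6 * (c_g / l_g) / sum_g(c_g / l_g)`; values sum to 1e6.
#'
#' @param counts Non-negative per-gene counts.
#' @param lengths Gene lengths in bp (> 0).
#' @return Numeric TPM vector.
#' @export
compute_tpm <- function(counts, lengths) {
  if (length(counts) != length(lengths))
    stop("counts and lengths must have equal length")
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  if (sum(counts) == 0) stop("all-zero counts")
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}

#' Summarize expression fold change by gene group
#'
#' Per-gene `log2((tpm_kd + eps) / (tpm_ctrl + eps))`, summarized per group
#' with quartiles and a two-sided Wilcoxon signed-rank test against zero
#' (are fold changes symmetric around zero?).
#'
#' @param tpm_ctrl,tpm_kd TPM vectors over the same gene universe.
#' @param groups Factor-like per-gene grouping (e.g. the `category` column
#'   of [classify_genes_by_sites()], or expression quartiles).
#' @param eps TPM pseudocount stabilizing silent genes (default 1).
#' @return List: `per_gene` data.frame (`group`, `log2fc`), `summary`
#'   data.frame (`group`, `n`, `median`, `q25`, `q75`, `p_wilcoxon`).
#' @export
expression_group_summary <- function(tpm_ctrl, tpm_kd, groups, eps = 1) {
  if (length(tpm_ctrl) != length(tpm_kd) ||
      length(tpm_ctrl) != length(groups))
    stop("tpm_ctrl, tpm_kd and groups must be parallel vectors")
  groups <- as.character(groups)
  l2fc <- log2((tpm_kd + eps) / (tpm_ctrl + eps))
  per_gene <- data.frame(group = groups, log2fc = l2fc,
                         stringsAsFactors = FALSE)
  gs <- unique(groups)
  rows <- lapply(gs, function(g) {
    v <- l2fc[groups == g]
    if (length(v) == 0) stop("empty group: ", g)
    p <- if (all(v == 0)) 1 else
      suppressWarnings(stats::wilcox.test(v, mu = 0)$p.value)
    data.frame(group = g, n = length(v),
               median = stats::median(v),
               q25 = as.numeric(stats::quantile(v, 0.25)),
               q75 = as.numeric(stats::quantile(v, 0.75)),
               p_wilcoxon = p, stringsAsFactors = FALSE)
  })
  list(per_gene = per_gene, summary = do.call(rbind, rows))
}
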