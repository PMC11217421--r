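#' Synthetic-data generators
#'
#' Seeded generators that emulate the statistical structure of each input
#' the pipeline consumes: binned DamID counts with planted LADs and
#' NPC-site dips, distance-decay Hi-C maps with planted TADs, compartments
#' and anchor sites, FISH/intensity nuclear-geometry tables, negative
#' binomial expression counts with planted class effects, and A/T-island
#' genome sequence. Identical seeds reproduce bit-identical outputs.
#'
#' @name synthetic_data
NULL

default_layout <- function(n_chrom = 2, chrom_len = 2e6) {
  genome_layout(paste0("chrS", seq_len(n_chrom)), rep(chrom_len, n_chrom))
}

## Plant alternating LADs/inter-LADs and site intervals used by the default
## DamID simulation. LADs of ~100 kb alternating with ~80-kb inter-LADs;
## NPC-like sites of 2 kb deep inside LADs; nucleoplasmic sites of 2 kb in
## inter-LADs.
default_damid_truth <- function(layout, lad_len = 1e5, gap_len = 8e4,
                                site_len = 2e3) {
  lens <- layout_lengths(layout)
  lad_l <- list(); npc_l <- list(); nucl_l <- list()
  for (cn in names(lens)) {
    L <- lens[[cn]]
    starts <- seq(gap_len, L - lad_len - 1, by = lad_len + gap_len)
    lad_l[[cn]] <- data.frame(chrom = cn, start = starts,
                              end = starts + lad_len)
    npc_l[[cn]] <- data.frame(chrom = cn,
                              start = starts + lad_len / 2 - site_len / 2,
                              end = starts + lad_len / 2 + site_len / 2)
    mid_gap <- starts - gap_len / 2 - site_len / 2
    nucl_l[[cn]] <- data.frame(chrom = cn, start = mid_gap,
                               end = mid_gap + site_len)
  }
  lads <- do.call(rbind, lad_l); npc <- do.call(rbind, npc_l)
  nucl <- do.call(rbind, nucl_l)
  list(lads = bp_interval(lads$chrom, lads$start, lads$end, layout = layout),
       npc_sites = bp_interval(npc$chrom, npc$start, npc$end,
                               layout = layout),
       nucl_sites = bp_interval(nucl$chrom, nucl$start, nucl$end,
                                layout = layout))
}

#' Parameters for the DamID count simulation
#'
#' @param layout Genome layout (default: 2 synthetic chromosomes of 2 Mb).
#' @param bin_size Bin width in bp (default 300).
#' @param lads,npc_sites,nucl_sites Planted intervals (`GRanges`); defaults
#'   plant alternating ~100-kb LADs with NPC-like sites at their centers
#'   and nucleoplasmic sites between LADs.
#' @param signal Which fusion protein the track emulates: `"lam"` (high in
#'   LADs, with local dips at NPC sites, emulating NPC-bound regions
#'   escaping the lamina) or `"elys"` (enriched at both site classes).
#' @param lad_log2,bg_log2 Planted mean log2 enrichment inside/outside LADs
#'   (defaults +1.2 / -1.2).
#' @param dip_log2 Depth of the Lam-signal dip at NPC sites in log2 units
#'   (default 1.0: a clear dip in averaged profiles that a 2-state domain
#'   caller still merges across, so NPC sites stay embedded within called
#'   LADs as they do in real maps).
#' @param site_log2 Elys enrichment at planted sites (default +1.5).
#' @param noise_sd Per-bin Gaussian spread of the planted log2 signal
#'   (default 0.4).
#' @param accessibility_sd Log-normal spread of shared per-bin
#'   accessibility affecting Dam and fusion alike (default 0.35, strong
#'   enough that replicate tracks are highly correlated, as real binned
#'   DamID counts are).
#' @param depth Sequencing depth per sample (total counts; default 1e6).
#' @param n_rep Biological replicates per sample (default 2).
#' @param seed Integer seed.
#' @return List of class `damid_sim_params`.
#' @export
damid_sim_params <- function(layout = default_layout(), bin_size = 300,
                             lads = NULL, npc_sites = NULL,
                             nucl_sites = NULL,
                             signal = c("lam", "elys"),
                             lad_log2 = 1.2, bg_log2 = -1.2,
                             dip_log2 = 1.0, site_log2 = 1.5,
                             noise_sd = 0.4, accessibility_sd = 0.35,
                             depth = 1e6, n_rep = 2, seed = 0) {
  signal <- match.arg(signal)
  if (depth <= 0) stop("depth must be > 0")
  if (n_rep < 1) stop("n_rep must be >= 1")
  truth <- default_damid_truth(layout)
  if (is.null(lads)) lads <- truth$lads
  if (is.null(npc_sites)) npc_sites <- truth$npc_sites
  if (is.null(nucl_sites)) nucl_sites <- truth$nucl_sites
  for (gr in list(lads, npc_sites, nucl_sites)) check_on_layout(gr, layout)
  structure(list(layout = layout, bin_size = bin_size, lads = lads,
                 npc_sites = npc_sites, nucl_sites = nucl_sites,
                 signal = signal, lad_log2 = lad_log2, bg_log2 = bg_log2,
                 dip_log2 = dip_log2, site_log2 = site_log2,
                 noise_sd = noise_sd, accessibility_sd = accessibility_sd,
                 depth = depth, n_rep = n_rep, seed = seed),
            class = "damid_sim_params")
}

bins_in <- function(bins, gr) {
  GenomicRanges::countOverlaps(bins, gr, ignore.strand = TRUE,
                               minoverlap = 1L) > 0
}

#' Simulate binned DamID counts
#'
#' Builds a planted per-bin log2 enrichment signal (LAD/background levels
#' with dips at NPC sites for the lamina signal, or site enrichment for the
#' Elys-like signal), adds per-bin Gaussian noise, and draws per-replicate
#' counts from a multinomial over bins: the Dam-only sample follows a
#' shared accessibility field, the fusion sample follows accessibility
#' times `2^signal`. Totals equal the requested depth exactly.
#'
#' @param p A [damid_sim_params()].
#' @return List: `fusion`, `dam` (lists of replicate count
#'   [binned_track()]s), `truth` (planted intervals and the noiseless
#'   per-bin log2 signal as a track).
#' @export
simulate_damid_counts <- function(p) {
  force(p)  # force before the RNG snapshot (lazy args)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(p$seed)
  bins <- bin_genome(p$layout, p$bin_size)
  nb <- length(bins)
  in_lad <- bins_in(bins, p$lads)
  in_npc <- bins_in(bins, p$npc_sites)
  in_nucl <- bins_in(bins, p$nucl_sites)

  if (p$signal == "lam") {
    sig <- ifelse(in_lad, p$lad_log2, p$bg_log2)
    sig[in_npc] <- sig[in_npc] - p$dip_log2
  } else {
    sig <- rep(p$bg_log2, nb)
    sig[in_npc | in_nucl] <- p$site_log2
  }
  noise <- stats::rnorm(nb, 0, p$noise_sd)
  access <- exp(stats::rnorm(nb, 0, p$accessibility_sd))
  w_fusion <- access * 2^(sig + noise)
  w_dam <- access

  draw <- function(w) {
    cnt <- stats::rmultinom(1, size = p$depth, prob = w / sum(w))[, 1]
    binned_track(p$layout, p$bin_size, as.numeric(cnt))
  }
  fusion <- lapply(seq_len(p$n_rep), function(i) draw(w_fusion))
  dam <- lapply(seq_len(p$n_rep), function(i) draw(w_dam))
  list(fusion = fusion, dam = dam,
       truth = list(lads = p$lads, npc_sites = p$npc_sites,
                    nucl_sites = p$nucl_sites,
                    signal_log2 = binned_track(p$layout, p$bin_size, sig)))
}

#' Parameters for the Hi-C contact-map simulation
#'
#' @param chrom Chromosome name (default `"chrS1"`).
#' @param chrom_len Chromosome length in bp (default 2 Mb).
#' @param bin_size Bin width in bp (default 2000).
#' @param alpha Distance-decay exponent: expected contacts follow
#'   `s^-alpha` (default 1).
#' @param tad_boundaries Sorted 0-based bp positions of planted TAD
#'   boundaries; every segment between consecutive boundaries (and the
#'   chromosome ends) is a TAD. The default plants boundaries every
#'   ~50 bins. Use `numeric(0)` for an explicit no-TAD map.
#' @param tad_intervals Alternative to `tad_boundaries`: a data.frame with
#'   bp columns `start`, `end` (0-based half-open); only these blocks are
#'   treated as TADs, the rest of the map is background.
#' @param tad_multiplier Within-TAD contact multiplier (default 2).
#' @param compartment_blocks Block length in bp of the alternating planted
#'   A/B checkerboard; `NA` disables compartments (default 2e5).
#' @param comp_strength Same-compartment contacts are multiplied by
#'   `1 + comp_strength` and cross-compartment contacts divided by it
#'   (default 0.25, a same/cross contact ratio of about 1.6: checkerboard
#'   contrast well below the within-TAD enrichment, as in real fly maps).
#' @param anchors 0-based bp positions of planted anchor sites whose
#'   cross-anchor contacts (offsets 1-4 bins on each side) are boosted;
#'   default plants one per ~500 kb.
#' @param anchor_boost Cross-anchor contact multiplier (default 2).
#' @param bb_boost Extra multiplier on B-B compartment contacts, emulating
#'   a knockdown that strengthens inactive-chromatin contacts (default 1).
#' @param total Total contact count (default 2e6, deep enough for stable
#'   TAD boundaries on a 2-Mb chromosome).
#' @param seed Integer seed.
#' @return List of class `hic_sim_params`.
#' @export
hic_sim_params <- function(chrom = "chrS1", chrom_len = 2e6,
                           bin_size = 2000, alpha = 1,
                           tad_boundaries = NULL, tad_intervals = NULL,
                           tad_multiplier = 2,
                           compartment_blocks = 2e5, comp_strength = 0.25,
                           anchors = NULL, anchor_boost = 2, bb_boost = 1,
                           total = 2e6, seed = 0) {
  if (tad_multiplier <= 0 || anchor_boost <= 0 || bb_boost <= 0)
    stop("multipliers must be > 0")
  n <- floor(chrom_len / bin_size)
  if (is.null(tad_boundaries) && is.null(tad_intervals))
    tad_boundaries <- seq(50, n - 1, by = 50) * bin_size
  if (!is.null(tad_boundaries)) {
    if (is.unsorted(tad_boundaries)) stop("tad_boundaries must be sorted")
    if (any(tad_boundaries < 0 | tad_boundaries > chrom_len))
      stop("tad_boundaries outside chromosome")
  }
  if (!is.null(tad_intervals) &&
      any(tad_intervals$start < 0 | tad_intervals$end > chrom_len))
    stop("tad_intervals outside chromosome")
  if (is.null(anchors))
    anchors <- seq(125, n - 1, by = 250) * bin_size
  if (any(anchors < 0 | anchors >= chrom_len))
    stop("anchors outside chromosome")
  structure(list(chrom = chrom, chrom_len = chrom_len, bin_size = bin_size,
                 alpha = alpha, tad_boundaries = tad_boundaries,
                 tad_intervals = tad_intervals,
                 tad_multiplier = tad_multiplier,
                 compartment_blocks = compartment_blocks,
                 comp_strength = comp_strength, anchors = anchors,
                 anchor_boost = anchor_boost, bb_boost = bb_boost,
                 total = total, seed = seed),
            class = "hic_sim_params")
}

#' Simulate an intra-chromosomal Hi-C contact matrix
#'
#' The expected intensity decays as `s^-alpha` with bin separation `s`,
#' within-TAD cells are multiplied by `tad_multiplier`, an alternating A/B
#' checkerboard modulates same- vs cross-compartment contacts, and each
#' planted anchor receives a cross-anchor boost spanning offsets 1-4 bins
#' on each side (creating a local ISm peak). Counts are Poisson draws
#' around the intensity scaled to the requested total; the matrix is
#' symmetric by construction.
#'
#' @param p A [hic_sim_params()].
#' @return List: `cm` (a [contact_matrix()]), `truth` (TAD boundaries and
#'   intervals in bins, per-bin compartment labels, anchor bins).
#' @export
simulate_hic <- function(p) {
  force(p)  # force before the RNG snapshot (lazy args)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(p$seed)
  n <- floor(p$chrom_len / p$bin_size)
  s <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- ifelse(s == 0, 2, s^(-p$alpha))

  if (!is.null(p$tad_intervals)) {
    b_bins <- integer(0)
    tads <- data.frame(
      start_bin = floor(p$tad_intervals$start / p$bin_size) + 1L,
      end_bin = pmin(ceiling(p$tad_intervals$end / p$bin_size), n))
    for (t in seq_len(nrow(tads))) {
      idx <- tads$start_bin[t]:tads$end_bin[t]
      E[idx, idx] <- E[idx, idx] * p$tad_multiplier
    }
  } else {
    b_bins <- unique(pmin(pmax(floor(p$tad_boundaries / p$bin_size), 0), n))
    edges <- sort(unique(c(0, b_bins, n)))
    tad_id <- cut(seq_len(n) - 0.5, breaks = edges, labels = FALSE)
    same_tad <- outer(tad_id, tad_id, "==")
    if (length(edges) > 2) E[same_tad] <- E[same_tad] * p$tad_multiplier
    tads <- data.frame(start_bin = utils::head(edges, -1) + 1L,
                       end_bin = edges[-1])
  }

  comp <- rep(NA_character_, n)
  if (is.finite(p$compartment_blocks)) {
    block <- max(1L, floor(p$compartment_blocks / p$bin_size))
    comp <- rep(c("A", "B"), each = block, length.out = n)
    same_comp <- outer(comp, comp, "==")
    E[same_comp] <- E[same_comp] * (1 + p$comp_strength)
    E[!same_comp] <- E[!same_comp] / (1 + p$comp_strength)
    if (p$bb_boost != 1) {
      bb <- outer(comp == "B", comp == "B", "&")
      E[bb] <- E[bb] * p$bb_boost
    }
  }

  anchor_bins <- floor(p$anchors / p$bin_size) + 1L
  for (a in anchor_bins) {
    u <- (a - 4):(a - 1); v <- (a + 1):(a + 4)
    u <- u[u >= 1]; v <- v[v <= n]
    if (length(u) && length(v)) {
      E[u, v] <- E[u, v] * p$anchor_boost
      E[v, u] <- E[v, u] * p$anchor_boost
    }
  }

  up <- upper.tri(E, diag = TRUE)
  lambda <- E[up] / sum(E[up]) * p$total
  counts <- stats::rpois(length(lambda), lambda)
  mat <- matrix(0, n, n)
  mat[up] <- counts
  mat <- mat + t(mat)
  diag(mat) <- diag(mat) / 2
  list(cm = contact_matrix(p$chrom, p$bin_size, mat),
       truth = list(boundary_bins = b_bins, tads = tads,
                    compartments = comp, anchor_bins = anchor_bins))
}

#' Parameters for the nuclear-geometry simulation
#'
#' @param n_nuclei Number of nuclei (default 100).
#' @param mean_radius,radius_sd Nuclear radius distribution in um
#'   (defaults 2.5 and 0.25; radii are truncated at 0.5 um).
#' @param model `"attached"` (locus concentrated near the envelope;
#'   normalized distance centered at `attached_center`) or `"detached"`
#'   (shifted inward by `shift`).
#' @param attached_center Median normalized distance of the attached model
#'   (default 0.1).
#' @param shift Inward shift of the detached model in radius units
#'   (default 0.1).
#' @param distance_sd Spread of the normalized distances (default 0.05).
#' @param chromatin `"peripheral"` (intensity peaks near both envelope
#'   ends) or `"displaced"` (intensity moved toward the interior), for the
#'   diameter profiles.
#' @param n_points Samples per diameter profile (default 64).
#' @param noise_sd Additive intensity noise (default 0.05).
#' @param condition Free-text condition label.
#' @param seed Integer seed.
#' @return List of class `geometry_sim_params`.
#' @export
geometry_sim_params <- function(n_nuclei = 100, mean_radius = 2.5,
                                radius_sd = 0.25,
                                model = c("attached", "detached"),
                                attached_center = 0.1, shift = 0.1,
                                distance_sd = 0.05,
                                chromatin = c("peripheral", "displaced"),
                                n_points = 64, noise_sd = 0.05,
                                condition = NULL, seed = 0) {
  model <- match.arg(model)
  chromatin <- match.arg(chromatin)
  if (mean_radius <= 0) stop("mean_radius must be > 0")
  if (n_points < 16) stop("n_points must be >= 16")
  if (is.null(condition)) condition <- model
  structure(list(n_nuclei = n_nuclei, mean_radius = mean_radius,
                 radius_sd = radius_sd, model = model,
                 attached_center = attached_center, shift = shift,
                 distance_sd = distance_sd, chromatin = chromatin,
                 n_points = n_points, noise_sd = noise_sd,
                 condition = condition, seed = seed),
            class = "geometry_sim_params")
}

#' Simulate FISH distances and diameter intensity profiles
#'
#' Radii are Gaussian (truncated at 0.5 um); normalized locus-to-envelope
#' distances are Gaussian around `attached_center` (plus `shift` for the
#' detached model), truncated to `[0, 1]`. Each nucleus also gets a
#' diameter profile pair: an envelope-marker channel with peaks at both
#' ends and a chromatin channel that is either peripheral (end peaks) or
#' displaced toward the interior.
#'
#' @param p A [geometry_sim_params()].
#' @return List: `nuclei` data.frame (`id`, `condition`, `volume`,
#'   `radius`, `distance`, `norm_distance`), `profiles` (list of
#'   `list(signal, ne)`).
#' @export
simulate_geometry <- function(p) {
  force(p)  # force before the RNG snapshot (lazy args)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(p$seed)
  r <- pmax(stats::rnorm(p$n_nuclei, p$mean_radius, p$radius_sd), 0.5)
  center <- p$attached_center + if (p$model == "detached") p$shift else 0
  nd <- stats::rnorm(p$n_nuclei, center, p$distance_sd)
  nd <- pmin(pmax(nd, 0), 1)
  vol <- 4 / 3 * pi * r^3

  x <- seq(0, 1, length.out = p$n_points)
  peak <- function(center, width) exp(-(x - center)^2 / (2 * width^2))
  profiles <- lapply(seq_len(p$n_nuclei), function(i) {
    ne <- 0.15 + peak(0.05, 0.03) + peak(0.95, 0.03) +
      stats::rnorm(p$n_points, 0, p$noise_sd)
    sig <- if (p$chromatin == "peripheral") {
      0.3 + 0.9 * (peak(0.10, 0.06) + peak(0.90, 0.06)) +
        0.2 * peak(0.5, 0.25)
    } else {
      0.3 + 0.35 * (peak(0.16, 0.08) + peak(0.84, 0.08)) +
        0.9 * peak(0.5, 0.25)
    }
    sig <- sig + stats::rnorm(p$n_points, 0, p$noise_sd)
    list(signal = pmax(sig, 0.01), ne = pmax(ne, 0.01))
  })
  nuclei <- data.frame(id = seq_len(p$n_nuclei), condition = p$condition,
                       volume = vol, radius = r, distance = nd * r,
                       norm_distance = nd)
  list(nuclei = nuclei, profiles = profiles)
}

#' Parameters for the expression-count simulation
#'
#' @param n_genes Genes per category (default 200), for categories
#'   `NPC_only`, `nucl_only`, `combination`, `none`.
#' @param mean_log_mu,sd_log_mu Log-normal distribution of baseline
#'   expression means (defaults 4 and 1).
#' @param dispersion Negative-binomial size parameter (default 10; larger
#'   = less overdispersed).
#' @param planted_l2fc Named planted log2 fold changes per category in the
#'   knockdown; default boosts `NPC_only` genes by +0.5 (NPC-class genes
#'   are up-regulated when the anchor is lost).
#' @param gene_length_range Gene lengths drawn uniformly from this bp range
#'   (default 1000-10000).
#' @param lib_sizes Library-size factors for the four samples (ctrl x2,
#'   kd x2).
#' @param seed Integer seed.
#' @return List of class `expression_sim_params`.
#' @export
expression_sim_params <- function(n_genes = 200, mean_log_mu = 4,
                                  sd_log_mu = 1, dispersion = 10,
                                  planted_l2fc = c(NPC_only = 0.5,
                                                   nucl_only = 0,
                                                   combination = 0,
                                                   none = 0),
                                  gene_length_range = c(1000, 10000),
                                  lib_sizes = c(1, 1.1, 0.95, 1.05),
                                  seed = 0) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (length(lib_sizes) != 4) stop("need 4 library-size factors")
  structure(list(n_genes = n_genes, mean_log_mu = mean_log_mu,
                 sd_log_mu = sd_log_mu, dispersion = dispersion,
                 planted_l2fc = planted_l2fc,
                 gene_length_range = gene_length_range,
                 lib_sizes = lib_sizes, seed = seed),
            class = "expression_sim_params")
}

#' Simulate expression counts for two conditions
#'
#' Negative-binomial counts for two replicates each of control and
#' knockdown; knockdown means are multiplied by `2^planted_l2fc` of the
#' gene's category.
#'
#' @param p An [expression_sim_params()].
#' @return List: `counts` (genes x 4 matrix, columns `ctrl_1`, `ctrl_2`,
#'   `kd_1`, `kd_2`), `genes` data.frame (`gene_id`, `category`, `length`,
#'   `mu`).
#' @export
simulate_expression <- function(p) {
  force(p)  # force before the RNG snapshot (lazy args)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(p$seed)
  cats <- names(p$planted_l2fc)
  category <- rep(cats, each = p$n_genes)
  ng <- length(category)
  mu <- exp(stats::rnorm(ng, p$mean_log_mu, p$sd_log_mu))
  len <- round(stats::runif(ng, p$gene_length_range[1],
                            p$gene_length_range[2]))
  if (any(is.na(len) | len <= 0)) stop("missing gene lengths")
  fc <- 2^p$planted_l2fc[category]
  draw <- function(m, sf) stats::rnbinom(ng, mu = m * sf,
                                         size = p$dispersion)
  counts <- cbind(ctrl_1 = draw(mu, p$lib_sizes[1]),
                  ctrl_2 = draw(mu, p$lib_sizes[2]),
                  kd_1 = draw(mu * fc, p$lib_sizes[3]),
                  kd_2 = draw(mu * fc, p$lib_sizes[4]))
  genes <- data.frame(gene_id = paste0("g", seq_len(ng)),
                      category = category, length = len, mu = mu)
  list(counts = counts, genes = genes)
}

#' Simulate genome sequence with planted A/T-rich islands
#'
#' Background bases are drawn uniformly (about 50% A/T); island intervals
#' are overwritten with strongly A/T-biased draws.
#'
#' @param layout A [genome_layout()].
#' @param at_islands `GRanges` of island intervals on the layout.
#' @param seed Integer seed.
#' @param island_at Per-base A/T probability inside islands (default 0.99,
#'   giving island windows >= 95% A/T essentially always).
#' @param background_at Per-base A/T probability outside (default 0.5).
#' @return A named `DNAStringSet`, one sequence per chromosome.
#' @export
simulate_sequence <- function(layout, at_islands, seed = 0,
                              island_at = 0.99, background_at = 0.5) {
  check_on_layout(at_islands, layout)
  seed <- as.integer(seed)  # force before the RNG snapshot (lazy args)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lens <- layout_lengths(layout)
  bg_prob <- c(A = background_at / 2, T = background_at / 2,
               C = (1 - background_at) / 2, G = (1 - background_at) / 2)
  isl_prob <- c(A = island_at / 2, T = island_at / 2,
                C = (1 - island_at) / 2, G = (1 - island_at) / 2)
  seqs <- lapply(names(lens), function(cn) {
    base <- sample(names(bg_prob), lens[[cn]], replace = TRUE,
                   prob = bg_prob)
    isl <- at_islands[as.character(GenomeInfoDb::seqnames(at_islands)) == cn]
    for (i in seq_along(isl)) {
      s <- GenomicRanges::start(isl)[i]; e <- GenomicRanges::end(isl)[i]
      base[s:e] <- sample(names(isl_prob), e - s + 1, replace = TRUE,
                          prob = isl_prob)
    }
    paste(base, collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(lens)
  out
}
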