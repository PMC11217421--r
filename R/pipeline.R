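#' Pipeline configuration
#'
#' Bundles every tunable of the workflow with its standard default: 300-bp
#' DamID bins, 2-state lamina / 3-state Elys HMMs, 900-bp gap filling,
#' 10,000 permutations, TAD-calling gamma = 1, Jacc group thresholds
#' +-0.8, 50 saddle quantiles with 1% trim and 10 extreme quantiles,
#' 2-kb ISm resolution, and the 0.15R peripheral zone.
#'
#' @param seed Master seed; each stage derives its own sub-seed from it.
#' @param ... Overrides for any config entry.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 0, ...) {
  cfg <- list(
    seed = seed,
    bin_size = 300,
    pseudocount = 1,
    hmm_states_lam = 2,
    hmm_states_elys = 3,
    max_gap = 900,
    min_overlap = 1,
    n_perm = 10000,
    profile_flank = 2000,
    lad_margin = 2000,
    at_flank = 150,
    at_window = 20,
    at_min_fraction = 0.9,
    hic_bin_size = 2000,
    tad_rebin = 2,           # 2-kb maps aggregated to 4-kb for TAD calling
    comp_rebin = 5,          # and to 10-kb for compartments
    gamma = 1,
    min_separation = 1000,
    jacc_threshold = 0.8,
    saddle_quantiles = 50,
    saddle_trim = 0.01,
    saddle_k = 10,
    ism_flank_bins = 10,
    pileup_flank_bins = 10,
    zone = 0.15,
    tpm_eps = 1,
    metagene_body_bins = 100)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = c("pipeline_config", "list"))
}

stage_seed <- function(cfg, offset) (cfg$seed * 97 + offset) %% 2147483647

#' Run the full synthetic-data workflow
#'
#' Generates every input with the synthetic generators, then runs all
#' analysis stages: DamID normalization and HMM domain calling (LADs and
#' Elys-like sites), site classification with permutation enrichment,
#' anchor-averaged signal and A/T profiles, the Hi-C battery (balancing,
#' O/E, TADs, Jacc groups, ACF log2FC, ISm, compartments/saddles,
#' pileups) for a control and an inactive-contact-boosted knockdown map,
#' nuclear-geometry statistics, and the expression group summary.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Nested report list of class `pipeline_report`; see the stage
#'   elements `damid`, `classification`, `profiles`, `hic`, `geometry`,
#'   `expression`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()

  ## -- simulate + call domains ------------------------------------------
  say("stage damid: simulate counts, normalize, call domains")
  p_lam <- damid_sim_params(signal = "lam", seed = stage_seed(cfg, 1))
  sim_lam <- simulate_damid_counts(p_lam)
  p_elys <- damid_sim_params(signal = "elys", seed = stage_seed(cfg, 2))
  sim_elys <- simulate_damid_counts(p_elys)

  norm_lam <- normalize_damid(sim_lam$fusion, sim_lam$dam,
                              pseudocount = cfg$pseudocount)
  norm_elys <- normalize_damid(sim_elys$fusion, sim_elys$dam,
                               pseudocount = cfg$pseudocount)
  hmm_lam <- fit_hmm(norm_lam$log2_ratio, n_states = cfg$hmm_states_lam)
  hmm_elys <- fit_hmm(norm_elys$log2_ratio, n_states = cfg$hmm_states_elys)
  lads <- fill_domain_gaps(
    states_to_domains(hmm_lam, norm_lam$log2_ratio$bins), cfg$max_gap)
  elys_sites <- fill_domain_gaps(
    states_to_domains(hmm_elys, norm_elys$log2_ratio$bins), cfg$max_gap)
  lad_f1 <- domain_f1(lads, sim_lam$truth$lads, p_lam$layout, cfg$bin_size)
  genome_bp <- sum(as.numeric(layout_lengths(p_lam$layout)))
  damid <- list(
    norm_lam = norm_lam, norm_elys = norm_elys,
    hmm_lam = hmm_lam, hmm_elys = hmm_elys,
    lads = lads, elys_sites = elys_sites,
    truth = sim_lam$truth,
    n_lads = length(lads), n_sites = length(elys_sites),
    median_site_bp = stats::median(GenomicRanges::width(elys_sites)),
    lad_fraction = sum(as.numeric(GenomicRanges::width(lads))) / genome_bp,
    lad_f1 = lad_f1)

  ## -- classify sites ----------------------------------------------------
  say("stage classify: site classes, permutation enrichment")
  layout <- p_lam$layout
  classes <- classify_sites(elys_sites, sim_lam$truth$npc_sites,
                            sim_lam$truth$nucl_sites,
                            min_overlap = cfg$min_overlap)
  class_frac <- prop.table(table(factor(
    S4Vectors::mcols(classes)$label,
    levels = c("Elys_NPC", "Elys_nucl", "Elys_NPC/nucl", "unassigned"))))
  perm <- permutation_overlap_test(
    elys_sites, sim_lam$truth$npc_sites, layout,
    n_perm = cfg$n_perm, seed = stage_seed(cfg, 3))
  npc_sites <- classes[S4Vectors::mcols(classes)$label == "Elys_NPC"]
  interior <- filter_interior_sites(npc_sites, lads,
                                    margin = cfg$lad_margin)
  classification <- list(
    classes = classes, class_fractions = as.numeric(class_frac),
    class_labels = names(class_frac), perm = perm,
    interior_npc_sites = interior)

  ## -- profiles ----------------------------------------------------------
  say("stage profiles: anchor, metagene, A/T")
  anchors <- if (length(interior)) interior else npc_sites
  lam_profile <- average_anchor_profile(norm_lam$log2_ratio, anchors,
                                        flank = cfg$profile_flank)
  genes <- synthetic_genes(layout)
  meta <- metagene_profile(norm_elys$log2_ratio, genes,
                           body_bins = cfg$metagene_body_bins,
                           flank = cfg$profile_flank)
  islands <- GenomicRanges::resize(sim_lam$truth$npc_sites, 40,
                                   fix = "center")
  seqs <- simulate_sequence(layout, islands, seed = stage_seed(cfg, 4))
  at_prof <- at_content_profile(seqs, sim_lam$truth$npc_sites,
                                flank = cfg$profile_flank,
                                window = cfg$at_window)
  at_frac <- at_rich_fraction(seqs, sim_lam$truth$npc_sites,
                              flank = cfg$at_flank,
                              window = cfg$at_window,
                              min_at_fraction = cfg$at_min_fraction)
  dip_depth <- profile_center_minus_flank(lam_profile)
  profiles <- list(lam_around_npc = lam_profile, metagene = meta,
                   at_profile = at_prof, at_rich_pct = at_frac,
                   lam_dip_depth = dip_depth)

  ## -- Hi-C --------------------------------------------------------------
  say("stage hic: balance, O/E, TADs, ACF, ISm, compartments")
  hp_ctrl <- hic_sim_params(seed = stage_seed(cfg, 5))
  ## knockdown map: anchor boost abolished, inactive-chromatin contacts
  ## modestly strengthened
  hp_kd <- hic_sim_params(seed = stage_seed(cfg, 6), anchor_boost = 1,
                          bb_boost = 1.15)
  sim_ctrl <- simulate_hic(hp_ctrl)
  sim_kd <- simulate_hic(hp_kd)
  hic <- hic_battery(sim_ctrl, sim_kd, lads, cfg, layout)

  ## -- geometry ----------------------------------------------------------
  say("stage geometry: FISH distances, diameter profiles")
  geo_ctrl <- simulate_geometry(geometry_sim_params(
    model = "attached", chromatin = "peripheral", condition = "control",
    seed = stage_seed(cfg, 7)))
  geo_kd <- simulate_geometry(geometry_sim_params(
    model = "detached", chromatin = "displaced", condition = "kd",
    seed = stage_seed(cfg, 8)))
  dist_test <- compare_distance_distributions(
    geo_ctrl$nuclei$norm_distance, geo_kd$nuclei$norm_distance)
  zone_test <- peripheral_zone_test(geo_ctrl$profiles, geo_kd$profiles,
                                    zone = cfg$zone)
  geometry <- list(ctrl = geo_ctrl, kd = geo_kd,
                   distance_test = dist_test, zone_test = zone_test)

  ## -- expression --------------------------------------------------------
  say("stage expression: TPM, group summary")
  ep <- expression_sim_params(seed = stage_seed(cfg, 9))
  sim_expr <- simulate_expression(ep)
  tpm_ctrl <- compute_tpm(rowSums(sim_expr$counts[, c("ctrl_1", "ctrl_2")]),
                          sim_expr$genes$length)
  tpm_kd <- compute_tpm(rowSums(sim_expr$counts[, c("kd_1", "kd_2")]),
                        sim_expr$genes$length)
  expr_summary <- expression_group_summary(tpm_ctrl, tpm_kd,
                                           sim_expr$genes$category,
                                           eps = cfg$tpm_eps)
  expression <- list(sim = sim_expr, tpm_ctrl = tpm_ctrl, tpm_kd = tpm_kd,
                     summary = expr_summary$summary,
                     per_gene = expr_summary$per_gene)

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  say(sprintf("pipeline finished in %.1f s", elapsed))
  structure(list(config = cfg, damid = damid,
                 classification = classification, profiles = profiles,
                 hic = hic, geometry = geometry, expression = expression,
                 elapsed_sec = elapsed),
            class = "pipeline_report")
}

## Hi-C stage shared by run_pipeline and the acceptance script.
hic_battery <- function(sim_ctrl, sim_kd, lads, cfg, layout) {
  prep <- function(sim) {
    cm <- remove_short_range(sim$cm, cfg$min_separation)
    bal2k <- iterative_correction(cm)
    oe2k <- observed_over_expected(bal2k)
    cm4k <- rebin_contacts(cm, cfg$tad_rebin)
    bal4k <- iterative_correction(cm4k)
    oe4k <- observed_over_expected(bal4k)
    cm10k <- rebin_contacts(cm, cfg$comp_rebin)
    bal10k <- iterative_correction(cm10k)
    oe10k <- observed_over_expected(bal10k)
    list(cm = cm, oe2k = oe2k, oe4k = oe4k, oe10k = oe10k,
         tads = call_tads(armatus_preprocess(bal4k), cfg$gamma))
  }
  ctrl <- prep(sim_ctrl)
  kd <- prep(sim_kd)

  shared <- match_tads(ctrl$tads, kd$tads)
  shared_tads <- ctrl$tads[shared$idx_a, , drop = FALSE]
  attr(shared_tads, "chrom") <- attr(ctrl$tads, "chrom")
  acf_fc <- if (nrow(shared_tads))
    acf_log2fc(kd$oe4k, ctrl$oe4k, shared_tads) else NULL

  active <- compartments_as_intervals(sim_ctrl$truth$compartments, "A",
                                      sim_ctrl$cm, layout)
  groups <- if (nrow(shared_tads))
    jaccard_group(shared_tads, lads_on(layout, lads, sim_ctrl$cm$chrom),
                  active, layout, chrom = sim_ctrl$cm$chrom,
                  threshold = cfg$jacc_threshold) else NULL

  anchors <- sim_ctrl$truth$anchor_bins
  ism_ctrl <- ism_profile(ctrl$oe2k)
  ism_kd <- ism_profile(kd$oe2k)
  ism_curve_ctrl <- averaged_ism_around(ism_ctrl, cfg$hic_bin_size,
                                        anchors, cfg$ism_flank_bins)
  ism_curve_kd <- averaged_ism_around(ism_kd, cfg$hic_bin_size,
                                      anchors, cfg$ism_flank_bins)

  comp_truth <- sim_ctrl$truth$compartments
  ori <- comp_orientation(comp_truth, cfg$comp_rebin, n_bins(ctrl$oe10k))
  pc1_ctrl <- compartment_pc1(ctrl$oe10k, ori)
  pc1_kd <- compartment_pc1(kd$oe10k, ori)
  sad_ctrl <- saddle(ctrl$oe10k, pc1_ctrl, cfg$saddle_quantiles,
                     cfg$saddle_trim)
  sad_kd <- saddle(kd$oe10k, pc1_kd, cfg$saddle_quantiles,
                   cfg$saddle_trim)
  sad_diff <- saddle_difference_summary(sad_kd, sad_ctrl, cfg$saddle_k)

  pu_ctrl <- pileup_oe(ctrl$oe2k, anchors, cfg$pileup_flank_bins)
  pu_kd <- pileup_oe(kd$oe2k, anchors, cfg$pileup_flank_bins)

  list(ctrl = ctrl, kd = kd, shared_tads = shared_tads,
       n_tads_ctrl = nrow(ctrl$tads), n_tads_kd = nrow(kd$tads),
       median_tad_bp = stats::median(ctrl$tads$end - ctrl$tads$start),
       acf_log2fc = acf_fc, groups = groups,
       ism = list(ctrl = ism_ctrl, kd = ism_kd,
                  curve_ctrl = ism_curve_ctrl, curve_kd = ism_curve_kd),
       pc1 = list(ctrl = pc1_ctrl, kd = pc1_kd),
       saddle = list(ctrl = sad_ctrl, kd = sad_kd, diff = sad_diff),
       pileup = list(ctrl = pu_ctrl, kd = pu_kd,
                     diff = pileup_difference(pu_kd, pu_ctrl)))
}

## The planted compartment labels of a simulated map as genomic intervals.
compartments_as_intervals <- function(comp, which_label, cm, layout) {
  if (all(is.na(comp))) return(GenomicRanges::GRanges())
  sel <- comp == which_label
  r <- rle(sel)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  bp_interval(rep(cm$chrom, length(keep)),
              (starts[keep] - 1) * cm$bin_size,
              ends[keep] * cm$bin_size, layout = layout)
}

## Restrict LADs to the Hi-C chromosome; returns an empty set when the
## DamID layout does not contain it (synthetic layouts may differ).
lads_on <- function(layout, lads, chrom) {
  sel <- as.character(GenomeInfoDb::seqnames(lads)) == chrom
  if (!any(sel)) GenomicRanges::GRanges() else lads[sel]
}

## Per-10kb-bin orientation signal = planted active-compartment indicator
## aggregated from the 2-kb truth labels.
comp_orientation <- function(comp, factor, n_out) {
  if (all(is.na(comp))) return(stats::runif(n_out))
  grp <- rep(seq_len(n_out), each = factor)[seq_along(comp)]
  as.numeric(tapply(comp == "A", grp, mean))[seq_len(n_out)]
}

## Base-level F1 of called domains against planted truth.
domain_f1 <- function(called, truth, layout, bin_size) {
  bins <- bin_genome(layout, bin_size)
  called_b <- bins_in(bins, called)
  truth_b <- bins_in(bins, truth)
  tp <- sum(called_b & truth_b)
  if (tp == 0) return(0)
  prec <- tp / sum(called_b)
  rec <- tp / sum(truth_b)
  2 * prec * rec / (prec + rec)
}

## Depth of the central dip of an anchor-averaged profile relative to its
## outer flanks (flank mean minus center mean; positive = dip).
profile_center_minus_flank <- function(prof) {
  n <- nrow(prof)
  center <- abs(prof$position) <= max(abs(prof$position)) * 0.15
  flank <- abs(prof$position) >= max(abs(prof$position)) * 0.7
  mean(prof$mean[flank], na.rm = TRUE) -
    mean(prof$mean[center], na.rm = TRUE)
}

## Plus/minus-strand genes tiling the inter-LAD regions of the default
## synthetic layout; used by the metagene stage.
synthetic_genes <- function(layout, gene_len = 8000, spacing = 30000) {
  lens <- layout_lengths(layout)
  rows <- list()
  for (cn in names(lens)) {
    starts <- seq(5000, lens[[cn]] - gene_len - 1, by = spacing)
    rows[[cn]] <- data.frame(chrom = cn, start = starts,
                             end = starts + gene_len)
  }
  tab <- do.call(rbind, rows)
  strand <- rep(c("+", "-"), length.out = nrow(tab))
  bp_interval(tab$chrom, tab$start, tab$end, strand = strand,
              layout = layout)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== synthetic peripheral-chromatin workflow report ==\n")
  cat(sprintf("DamID: %d LADs (%.1f%% of genome, F1 %.3f), %d sites ",
              x$damid$n_lads, 100 * x$damid$lad_fraction, x$damid$lad_f1,
              x$damid$n_sites))
  cat(sprintf("(median %.1f kb)\n", x$damid$median_site_bp / 1000))
  cf <- x$classification$class_fractions
  cat(sprintf("classes: %s\n", paste(sprintf(
    "%s %.0f%%", x$classification$class_labels, 100 * cf),
    collapse = ", ")))
  cat(sprintf("permutation: observed %d, p %s\n",
              x$classification$perm$observed,
              format(x$classification$perm$p_value, digits = 3)))
  cat(sprintf("profiles: Lam dip depth %.2f, A/T-rich sites %.1f%%\n",
              x$profiles$lam_dip_depth, x$profiles$at_rich_pct))
  cat(sprintf("Hi-C: %d/%d TADs (ctrl/kd), %d shared, median %.0f kb\n",
              x$hic$n_tads_ctrl, x$hic$n_tads_kd,
              nrow(x$hic$shared_tads), x$hic$median_tad_bp / 1000))
  if (!is.null(x$hic$acf_log2fc))
    cat(sprintf("  median ACF log2FC (kd/ctrl): %.3f\n",
                stats::median(x$hic$acf_log2fc$log2fc, na.rm = TRUE)))
  sd <- x$hic$saddle$diff$summary
  cat(sprintf("  saddle diff means: %s\n", paste(sprintf(
    "%s %.3f", sd$block, sd$mean), collapse = ", ")))
  cat(sprintf("geometry: distance p %s; peripheral-zone p %s\n",
              format(x$geometry$distance_test$p_value, digits = 3),
              format(x$geometry$zone_test$p_value, digits = 3)))
  es <- x$expression$summary
  cat("expression medians:",
      paste(sprintf("%s %.3f", es$group, es$median), collapse = ", "),
      "\n")
  cat(sprintf("elapsed: %.1f s\n", x$elapsed_sec))
  invisible(x)
}

#' Write the report's tables to a directory
#'
#' Emits plain-text TSV/BED outputs for each stage: domain BED files, the
#' site-classification table, permutation summary, profile tables, TAD and
#' group tables, ISm curves, saddle grids, pileups, geometry tables and
#' the expression summary.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_bed(report$damid$lads, file.path(dir, "lads.bed"))
  write_bed(report$damid$elys_sites, file.path(dir, "elys_sites.bed"))
  cl <- report$classification$classes
  w(data.frame(chrom = as.character(GenomeInfoDb::seqnames(cl)),
               start = GenomicRanges::start(cl) - 1,
               end = GenomicRanges::end(cl),
               label = S4Vectors::mcols(cl)$label),
    "site_classes.tsv")
  p <- report$classification$perm
  w(data.frame(observed = p$observed, null_mean = mean(p$null_counts),
               n_perm = p$n_perm, p_value = p$p_value),
    "permutation.tsv")
  w(report$profiles$lam_around_npc, "profile_lam_around_npc.tsv")
  w(report$profiles$metagene, "profile_metagene.tsv")
  w(report$profiles$at_profile, "profile_at_content.tsv")
  w(report$hic$ctrl$tads, "tads_ctrl.tsv")
  w(report$hic$kd$tads, "tads_kd.tsv")
  if (!is.null(report$hic$acf_log2fc))
    w(report$hic$acf_log2fc, "acf_log2fc.tsv")
  if (!is.null(report$hic$groups)) w(report$hic$groups, "tad_groups.tsv")
  w(report$hic$ism$curve_ctrl, "ism_curve_ctrl.tsv")
  w(report$hic$ism$curve_kd, "ism_curve_kd.tsv")
  w(as.data.frame(report$hic$saddle$ctrl$grid), "saddle_ctrl.tsv")
  w(as.data.frame(report$hic$saddle$kd$grid), "saddle_kd.tsv")
  w(report$hic$saddle$diff$summary, "saddle_diff_summary.tsv")
  w(as.data.frame(report$hic$pileup$diff), "pileup_diff.tsv")
  w(rbind(report$geometry$ctrl$nuclei, report$geometry$kd$nuclei),
    "nuclei.tsv")
  w(report$expression$summary, "expression_summary.tsv")
  invisible(dir)
}
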