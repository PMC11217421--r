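## The Hi-C battery on the control and knockdown maps: short-range
## filtering, balancing, O/E, TAD calling at 4-kb resolution with the
## Armatus objective, Jacc activity grouping, per-TAD ACF log2FC,
## modified insulation score around planted anchors at 2-kb resolution,
## compartment PC1 / saddles at 10-kb resolution, and anchor pileups.
source("analysis/00_common.R")

message("== 05: Hi-C compaction statistics ==")
layout <- read_chrom_sizes(file.path(RAW, "genome.chrom.sizes"))
cm_ctrl <- read_contacts_coo(file.path(RAW, "hic_ctrl.coo.tsv"))
cm_kd <- read_contacts_coo(file.path(RAW, "hic_kd.coo.tsv"))
anchors <- utils::read.delim(file.path(RAW, "truth_anchors.tsv"))$anchor_bin
comp <- utils::read.delim(file.path(RAW,
                                    "truth_compartments.tsv"))$compartment

prep <- function(cm) {
  cm <- remove_short_range(cm, cfg$min_separation)
  list(cm = cm,
       oe2k = observed_over_expected(iterative_correction(cm)),
       bal4k = iterative_correction(rebin_contacts(cm, cfg$tad_rebin)),
       oe10k = observed_over_expected(iterative_correction(
         rebin_contacts(cm, cfg$comp_rebin))))
}
ctrl <- prep(cm_ctrl)
kd <- prep(cm_kd)
ctrl$oe4k <- observed_over_expected(ctrl$bal4k)
kd$oe4k <- observed_over_expected(kd$bal4k)

tads_ctrl <- call_tads(armatus_preprocess(ctrl$bal4k), cfg$gamma)
tads_kd <- call_tads(armatus_preprocess(kd$bal4k), cfg$gamma)
shared <- match_tads(tads_ctrl, tads_kd)
message(sprintf(
  "TADs: %d control / %d knockdown, %d (%.0f%%) with identical boundaries",
  nrow(tads_ctrl), nrow(tads_kd), nrow(shared),
  100 * nrow(shared) / max(nrow(tads_ctrl), 1)))
write_tsv(tads_ctrl, file.path(RES, "tads_ctrl.tsv"))
write_tsv(tads_kd, file.path(RES, "tads_kd.tsv"))

## activity grouping of the shared TADs and ACF change
shared_tads <- tads_ctrl[shared$idx_a, , drop = FALSE]
attr(shared_tads, "chrom") <- cm_ctrl$chrom
lads <- read_bed(file.path(RES, "lads.bed"))
lads_here <- lads[as.character(seqnames(lads)) == cm_ctrl$chrom]
active <- perichrom:::compartments_as_intervals(comp, "A", cm_ctrl,
                                                layout)
fc <- acf_log2fc(kd$oe4k, ctrl$oe4k, shared_tads)
grp <- jaccard_group(cbind(shared_tads, log2fc = fc$log2fc),
                     lads_here, active, layout, chrom = cm_ctrl$chrom,
                     threshold = cfg$jacc_threshold)
write_tsv(grp, file.path(RES, "tad_groups_acf.tsv"))
for (g in sort(unique(grp$group)))
  message(sprintf("  group %s: %d TADs, median ACF log2FC %+0.3f", g,
                  sum(grp$group == g),
                  median(grp$log2fc[grp$group == g], na.rm = TRUE)))

## modified insulation score around the planted anchor bins
ism_ctrl <- ism_profile(ctrl$oe2k)
ism_kd <- ism_profile(kd$oe2k)
curve_ctrl <- averaged_ism_around(ism_ctrl, cfg$hic_bin_size, anchors,
                                  cfg$ism_flank_bins)
curve_kd <- averaged_ism_around(ism_kd, cfg$hic_bin_size, anchors,
                                cfg$ism_flank_bins)
write_tsv(curve_ctrl, file.path(RES, "ism_curve_ctrl.tsv"))
write_tsv(curve_kd, file.path(RES, "ism_curve_kd.tsv"))
c0 <- curve_ctrl$position == 0
message(sprintf(
  "ISm at anchors: control %.3f vs knockdown %.3f (flank ~%.3f)",
  curve_ctrl$mean[c0], curve_kd$mean[c0],
  mean(curve_ctrl$mean[abs(curve_ctrl$position) >= 16000])))

## compartments and saddles
ori <- perichrom:::comp_orientation(comp, cfg$comp_rebin,
                                    nrow(ctrl$oe10k$mat))
pc_ctrl <- compartment_pc1(ctrl$oe10k, ori)
pc_kd <- compartment_pc1(kd$oe10k, ori)
sad_ctrl <- saddle(ctrl$oe10k, pc_ctrl, cfg$saddle_quantiles,
                   cfg$saddle_trim)
sad_kd <- saddle(kd$oe10k, pc_kd, cfg$saddle_quantiles, cfg$saddle_trim)
diff <- saddle_difference_summary(sad_kd, sad_ctrl, cfg$saddle_k)
print(diff$summary, digits = 3)
write_tsv(diff$summary, file.path(RES, "saddle_diff_summary.tsv"))
utils::write.table(sad_ctrl$grid, file.path(RES, "saddle_ctrl.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)
utils::write.table(sad_kd$grid, file.path(RES, "saddle_kd.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)

## anchor pileups and their condition difference
pu_ctrl <- pileup_oe(ctrl$oe2k, anchors, cfg$pileup_flank_bins)
pu_kd <- pileup_oe(kd$oe2k, anchors, cfg$pileup_flank_bins)
pd <- pileup_difference(pu_kd, pu_ctrl)
utils::write.table(pd, file.path(RES, "pileup_diff.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE, col.names = FALSE)
center <- cfg$pileup_flank_bins + 1
message(sprintf(
  "pileup difference at the anchor cross: %+0.3f (kd - ctrl)",
  mean(pd[(center - 4):(center - 1), (center + 1):(center + 4)])))
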