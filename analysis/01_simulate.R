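## Generate every synthetic input the downstream stages consume and write
## them in the pipeline's on-disk formats (bedGraph counts, BED truth
## files, COO contact lists, FASTA, geometry and expression tables).
source("analysis/00_common.R")

message("== 01: simulating inputs (seed ", SEED, ") ==")

## DamID counts: lamina and Elys-like fusion, 2 replicates + Dam controls
p_lam <- damid_sim_params(signal = "lam",
                          seed = perichrom:::stage_seed(cfg, 1))
p_elys <- damid_sim_params(signal = "elys",
                           seed = perichrom:::stage_seed(cfg, 2))
sim_lam <- simulate_damid_counts(p_lam)
sim_elys <- simulate_damid_counts(p_elys)
write_chrom_sizes(p_lam$layout, file.path(RAW, "genome.chrom.sizes"))
for (i in 1:2) {
  write_track_bedgraph(sim_lam$fusion[[i]],
                       file.path(RAW, sprintf("lam_rep%d.bedGraph", i)))
  write_track_bedgraph(sim_lam$dam[[i]],
                       file.path(RAW, sprintf("dam_lam_rep%d.bedGraph", i)))
  write_track_bedgraph(sim_elys$fusion[[i]],
                       file.path(RAW, sprintf("elys_rep%d.bedGraph", i)))
  write_track_bedgraph(sim_elys$dam[[i]],
                       file.path(RAW, sprintf("dam_elys_rep%d.bedGraph", i)))
}
write_bed(sim_lam$truth$lads, file.path(RAW, "truth_lads.bed"))
write_bed(sim_lam$truth$npc_sites, file.path(RAW, "truth_npc_sites.bed"))
write_bed(sim_lam$truth$nucl_sites, file.path(RAW, "truth_nucl_sites.bed"))
message("DamID: 2x2 fusion/Dam replicate tracks + truth BEDs")

## Hi-C: control map with planted TADs/compartments/anchors; knockdown map
## with the anchor boost abolished and B-B contacts mildly strengthened
hp_ctrl <- hic_sim_params(seed = perichrom:::stage_seed(cfg, 5))
hp_kd <- hic_sim_params(seed = perichrom:::stage_seed(cfg, 6),
                        anchor_boost = 1, bb_boost = 1.15)
sim_ctrl <- simulate_hic(hp_ctrl)
sim_kd <- simulate_hic(hp_kd)
write_contacts_coo(sim_ctrl$cm, file.path(RAW, "hic_ctrl.coo.tsv"))
write_contacts_coo(sim_kd$cm, file.path(RAW, "hic_kd.coo.tsv"))
write_tsv(sim_ctrl$truth$tads, file.path(RAW, "truth_tads.tsv"))
write_tsv(data.frame(bin = seq_along(sim_ctrl$truth$compartments),
                     compartment = sim_ctrl$truth$compartments),
          file.path(RAW, "truth_compartments.tsv"))
write_tsv(data.frame(anchor_bin = sim_ctrl$truth$anchor_bins),
          file.path(RAW, "truth_anchors.tsv"))
message("Hi-C: ", sum(sim_ctrl$cm$mat) / 2, " ctrl contacts, ",
        nrow(sim_ctrl$truth$tads), " planted TADs")

## Genome sequence with A/T islands under the planted NPC sites
islands <- resize(sim_lam$truth$npc_sites, 40, fix = "center")
seqs <- simulate_sequence(p_lam$layout, islands,
                          seed = perichrom:::stage_seed(cfg, 4))
Biostrings::writeXStringSet(seqs, file.path(RAW, "genome.fa"))

## Nuclear geometry: attached/peripheral control vs detached/displaced KD
geo_ctrl <- simulate_geometry(geometry_sim_params(
  model = "attached", chromatin = "peripheral", condition = "control",
  seed = perichrom:::stage_seed(cfg, 7)))
geo_kd <- simulate_geometry(geometry_sim_params(
  model = "detached", chromatin = "displaced", condition = "kd",
  seed = perichrom:::stage_seed(cfg, 8)))
write_tsv(rbind(geo_ctrl$nuclei, geo_kd$nuclei),
          file.path(RAW, "nuclei.tsv"))
prof_rows <- do.call(rbind, lapply(seq_along(c(geo_ctrl$profiles,
                                               geo_kd$profiles)),
  function(i) {
    ps <- c(geo_ctrl$profiles, geo_kd$profiles)[[i]]
    cond <- if (i <= length(geo_ctrl$profiles)) "control" else "kd"
    data.frame(nucleus = i, condition = cond,
               position = seq_along(ps$signal),
               signal = ps$signal, ne = ps$ne)
  }))
write_tsv(prof_rows, file.path(RAW, "diameter_profiles.tsv"))
message("geometry: ", nrow(geo_ctrl$nuclei), "+", nrow(geo_kd$nuclei),
        " nuclei with diameter profiles")

## Expression counts
sim_expr <- simulate_expression(expression_sim_params(
  seed = perichrom:::stage_seed(cfg, 9)))
write_tsv(cbind(sim_expr$genes, sim_expr$counts),
          file.path(RAW, "expression_counts.tsv"))
message("expression: ", nrow(sim_expr$genes), " genes x 4 samples")
message("inputs written under ", RAW)
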