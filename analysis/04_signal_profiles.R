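## Anchor-averaged signal profiles (the lamina dip at NPC-class sites
## inside LADs), a metagene profile of the Elys-like signal, and the
## A/T-content analysis around site centers.
source("analysis/00_common.R")

message("== 04: averaged profiles and A/T content ==")
layout <- read_chrom_sizes(file.path(RAW, "genome.chrom.sizes"))
lam <- read_track_bedgraph(file.path(RES, "lam_log2.bedGraph"),
                           layout, cfg$bin_size)
elys <- read_track_bedgraph(file.path(RES, "elys_log2.bedGraph"),
                            layout, cfg$bin_size)
anchors <- read_bed(file.path(RES, "npc_sites_within_lads.bed"), layout)

prof <- average_anchor_profile(lam, anchors, flank = cfg$profile_flank)
dip <- perichrom:::profile_center_minus_flank(prof)
message(sprintf(
  "lamina profile around %d interior NPC-class sites: dip depth %.2f log2",
  length(anchors), dip))
write_tsv(prof, file.path(RES, "profile_lam_around_npc.tsv"))

genes <- perichrom:::synthetic_genes(layout)
meta <- metagene_profile(elys, genes,
                         body_bins = cfg$metagene_body_bins,
                         flank = cfg$profile_flank)
write_tsv(meta, file.path(RES, "profile_metagene_elys.tsv"))
message("metagene over ", length(genes), " genes written")

seqs <- Biostrings::readDNAStringSet(file.path(RAW, "genome.fa"))
npc_truth <- read_bed(file.path(RAW, "truth_npc_sites.bed"), layout)
at_prof <- at_content_profile(seqs, npc_truth,
                              flank = cfg$profile_flank,
                              window = cfg$at_window)
write_tsv(at_prof, file.path(RES, "profile_at_content.tsv"))
at_pct <- at_rich_fraction(seqs, npc_truth, flank = cfg$at_flank,
                           window = cfg$at_window,
                           min_at_fraction = cfg$at_min_fraction)
message(sprintf(
  "%.1f%% of NPC sites carry a >=90%% A/T 20-bp window within +-150 bp",
  at_pct))
writeLines(sprintf("at_rich_site_pct\t%.4f", at_pct),
           file.path(RES, "at_rich_fraction.txt"))
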