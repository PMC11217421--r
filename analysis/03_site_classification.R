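## Classify the called sites against the NPC / nucleoplasmic reference
## sets, test the NPC association by permutation, categorize genes by
## their site content, and summarize expression fold changes per category.
source("analysis/00_common.R")

message("== 03: site classification and enrichment ==")
layout <- read_chrom_sizes(file.path(RAW, "genome.chrom.sizes"))
sites <- read_bed(file.path(RES, "elys_sites.bed"), layout)
lads <- read_bed(file.path(RES, "lads.bed"), layout)
npc_ref <- read_bed(file.path(RAW, "truth_npc_sites.bed"), layout)
nucl_ref <- read_bed(file.path(RAW, "truth_nucl_sites.bed"), layout)

classes <- classify_sites(sites, npc_ref, nucl_ref,
                          min_overlap = cfg$min_overlap)
lab <- S4Vectors::mcols(classes)$label
tab <- table(factor(lab, levels = c("Elys_NPC", "Elys_nucl",
                                    "Elys_NPC/nucl", "unassigned")))
message("site classes: ",
        paste(sprintf("%s %.0f%%", names(tab), 100 * tab / sum(tab)),
              collapse = ", "))
write_tsv(data.frame(chrom = as.character(seqnames(classes)),
                     start = start(classes) - 1, end = end(classes),
                     label = lab),
          file.path(RES, "site_classes.tsv"))

perm <- permutation_overlap_test(sites, npc_ref, layout,
                                 n_perm = cfg$n_perm,
                                 seed = perichrom:::stage_seed(cfg, 3))
print(perm)
write_tsv(data.frame(observed = perm$observed,
                     null_mean = mean(perm$null_counts),
                     n_perm = perm$n_perm, p_value = perm$p_value),
          file.path(RES, "permutation_npc.tsv"))

npc_sites <- classes[lab == "Elys_NPC"]
interior <- filter_interior_sites(npc_sites, lads,
                                  margin = cfg$lad_margin)
message(length(interior), " of ", length(npc_sites),
        " NPC-class sites lie deep (>2 kb) inside LADs")
write_bed(interior, file.path(RES, "npc_sites_within_lads.bed"))

## genes and expression by site category
genes <- perichrom:::synthetic_genes(layout)
gene_cat <- classify_genes_by_sites(genes, classes)
message("gene categories: ",
        paste(names(table(gene_cat$category)),
              table(gene_cat$category), collapse = ", ", sep = ":"))

expr <- utils::read.delim(file.path(RAW, "expression_counts.tsv"))
tpm_ctrl <- compute_tpm(expr$ctrl_1 + expr$ctrl_2, expr$length)
tpm_kd <- compute_tpm(expr$kd_1 + expr$kd_2, expr$length)
es <- expression_group_summary(tpm_ctrl, tpm_kd, expr$category,
                               eps = cfg$tpm_eps)
print(es$summary, digits = 3)
write_tsv(es$summary, file.path(RES, "expression_summary.tsv"))
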