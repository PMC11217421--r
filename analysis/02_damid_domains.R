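## Normalize the binned DamID counts and call domains: a 2-state HMM on
## the lamina log-ratio gives LADs, a 3-state HMM on the Elys-like
## log-ratio gives binding sites; sub-900-bp gaps are filled.
source("analysis/00_common.R")

message("== 02: DamID normalization and domain calling ==")
layout <- read_chrom_sizes(file.path(RAW, "genome.chrom.sizes"))
rd <- function(stem) lapply(1:2, function(i) read_track_bedgraph(
  file.path(RAW, sprintf("%s_rep%d.bedGraph", stem, i)),
  layout, cfg$bin_size))

norm_lam <- normalize_damid(rd("lam"), rd("dam_lam"),
                            pseudocount = cfg$pseudocount)
norm_elys <- normalize_damid(rd("elys"), rd("dam_elys"),
                             pseudocount = cfg$pseudocount)
message("replicate correlations: lam ",
        round(norm_lam$replicate_cor[["fusion"]], 3), ", elys ",
        round(norm_elys$replicate_cor[["fusion"]], 3))
write_track_bedgraph(norm_lam$log2_ratio,
                     file.path(RES, "lam_log2.bedGraph"))
write_track_bedgraph(norm_elys$log2_ratio,
                     file.path(RES, "elys_log2.bedGraph"))

hmm_lam <- fit_hmm(norm_lam$log2_ratio, n_states = cfg$hmm_states_lam)
hmm_elys <- fit_hmm(norm_elys$log2_ratio, n_states = cfg$hmm_states_elys)
print(hmm_lam)
print(hmm_elys)

lads <- fill_domain_gaps(states_to_domains(hmm_lam,
                                           norm_lam$log2_ratio$bins),
                         cfg$max_gap)
sites <- fill_domain_gaps(states_to_domains(hmm_elys,
                                            norm_elys$log2_ratio$bins),
                          cfg$max_gap)
write_bed(lads, file.path(RES, "lads.bed"))
write_bed(sites, file.path(RES, "elys_sites.bed"))

truth_lads <- read_bed(file.path(RAW, "truth_lads.bed"), layout)
f1 <- perichrom:::domain_f1(lads, truth_lads, layout, cfg$bin_size)
genome_bp <- sum(as.numeric(seqlengths(layout)))
message(sprintf(
  "LADs: %d covering %.1f%% of the genome (recovery F1 %.3f)",
  length(lads), 100 * sum(as.numeric(width(lads))) / genome_bp, f1))
message(sprintf("Elys-like sites: %d, median %.1f kb",
                length(sites), median(width(sites)) / 1000))

## model parameter report
rep_lines <- c(
  sprintf("lam HMM (%d states): means %s, sds %s, loglik %.1f",
          hmm_lam$n_states,
          paste(round(hmm_lam$means, 3), collapse = "/"),
          paste(round(sqrt(hmm_lam$vars), 3), collapse = "/"),
          hmm_lam$loglik),
  sprintf("elys HMM (%d states): means %s, sds %s, loglik %.1f",
          hmm_elys$n_states,
          paste(round(hmm_elys$means, 3), collapse = "/"),
          paste(round(sqrt(hmm_elys$vars), 3), collapse = "/"),
          hmm_elys$loglik),
  sprintf("LAD recovery F1 vs planted truth: %.4f", f1))
writeLines(rep_lines, file.path(RES, "damid_model_report.txt"))
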