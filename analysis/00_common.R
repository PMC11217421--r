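## Shared setup for the analysis drivers: one seed, one results tree.
## Run the scripts in order from the repository root:
##   Rscript analysis/01_simulate.R
##   Rscript analysis/02_damid_domains.R
##   ...
suppressPackageStartupMessages({
  library(perichrom)
  library(GenomicRanges)
})

SEED <- as.integer(Sys.getenv("PERICHROM_SEED", "1"))
RES <- "results"
RAW <- file.path(RES, "synthetic")
dir.create(RAW, showWarnings = FALSE, recursive = TRUE)

cfg <- pipeline_config(seed = SEED)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
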