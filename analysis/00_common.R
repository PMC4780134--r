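# Shared setup for the numbered analysis scripts: run from the repository
# root, e.g.  Rscript analysis/01_simulate.R
# Outputs accumulate under results/; the seed can be overridden with the
# ANALYSIS_SEED environment variable.

suppressPackageStartupMessages(library(castenet))

SEED <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

res_path <- function(...) file.path(RESULTS, ...)

read_tsv <- function(path) read.table(path, header = TRUE, sep = "\t",
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE)
write_tsv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_counts_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
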