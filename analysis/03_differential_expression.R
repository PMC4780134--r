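# Stage 3: per-species queen-vs-worker differential expression.
#
# Within each species: low-count filter, TMM offsets, fixed-dispersion NB
# likelihood-ratio test at the transcript level, BH-FDR at 0.05, collapsed
# to OGGs by the member transcript with the smallest q.

source("analysis/00_common.R")

counts <- read_counts_matrix(res_path("data", "counts.tsv"))
samples <- read_tsv(res_path("data", "samples.tsv"))
ogg_map <- read_tsv(res_path("data", "ogg_map.tsv"))

summary_rows <- list()
for (sp in unique(samples$species)) {
  idx <- samples$species == sp
  sub <- counts[, samples$sample[idx], drop = FALSE]
  grp <- samples$caste[idx]
  sub <- sub[rowSums(!is.na(sub)) > 0, , drop = FALSE]
  sub <- low_count_filter(sub, min_count = 5, min_samples = 2, groups = grp)
  sub <- sub[rowSums(sub, na.rm = TRUE) > 0, , drop = FALSE]
  de_tx <- caste_de_test(sub, grp, alpha = 0.05)
  de_tx$ogg <- ogg_map$ogg[match(de_tx$gene, ogg_map$transcript)]
  de_tx <- de_tx[order(de_tx$ogg, is.na(de_tx$q), de_tx$q), ]
  de <- de_tx[!duplicated(de_tx$ogg), ]
  de$gene <- de$ogg
  write_tsv(de[, c("gene", "logFC", "p", "q", "direction")],
            res_path("de", paste0("de_", sp, ".tsv")))
  summary_rows[[sp]] <- data.frame(
    species = sp, tested = sum(!de$untestable),
    queen_biased = sum(de$direction == "queen"),
    worker_biased = sum(de$direction == "worker"))
}
smry <- do.call(rbind, summary_rows)
write_tsv(smry, res_path("de", "summary.tsv"))
print(smry, row.names = FALSE)
cat("Caste-biased OGGs per species: median",
    median(smry$queen_biased + smry$worker_biased), "\n")
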