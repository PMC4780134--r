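# Stage 6: cross-species consistency of caste-biased expression.
#
# Direction-aware intersection of per-species DE sets, the bootstrap
# overlap curve over random species subsets (100 draws per subset size),
# and a comparison of two species subsets of equal size.

source("analysis/00_common.R")

de_files <- list.files(res_path("de"), pattern = "^de_.*\\.tsv$",
                       full.names = TRUE)
de_list <- lapply(de_files, function(f) {
  d <- read_tsv(f)
  d$untestable <- FALSE
  d
})
names(de_list) <- sub("^de_(.*)\\.tsv$", "\\1", basename(de_files))

curve <- deg_overlap_curve(de_list, n_draws = 100, seed = SEED + 907)
consistent <- consistent_deg_set(de_list)
write_tsv(curve[, c("k", "mean", "sd")],
          res_path("overlap", "overlap_curve.tsv"))
write_tsv(consistent, res_path("overlap", "consistent_degs.tsv"))

cat("Mean shared caste-biased OGGs by number of species sampled:\n")
print(curve[, c("k", "mean", "sd")], row.names = FALSE, digits = 3)
cat(nrow(consistent),
    "OGG(s) consistently caste-biased across all species\n")

half <- floor(length(de_list) / 2)
cmp <- subset_overlap_compare(de_list, names(de_list)[seq_len(half)],
                              names(de_list)[seq_len(half) + half])
cat("Subset comparison: first", half, "species share", cmp$count_a,
    "; next", half, "species share", cmp$count_b, "\n")
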