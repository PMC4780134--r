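# Stage 2: build the OGG x sample expression matrix.
#
# TMM normalization of transcript counts, log2 counts-per-million,
# aggregation of transcripts to OGGs, removal of OGGs with excessive
# missingness or zero variance, outlier-sample screening, and MDS of the
# retained matrix.

source("analysis/00_common.R")

counts <- read_counts_matrix(res_path("data", "counts.tsv"))
samples <- read_tsv(res_path("data", "samples.tsv"))
ogg_map <- read_tsv(res_path("data", "ogg_map.tsv"))

factors <- tmm_factors(counts)
logcpm <- log2_cpm(counts, factors)
ogg_expr <- aggregate_to_ogg(logcpm, ogg_map)
flt <- filter_oggs(ogg_expr, max_missing_fraction = 0.5)
outliers <- detect_outlier_samples(flt$matrix, z_threshold = 3)
kept <- setdiff(colnames(flt$matrix), outliers)
mds <- mds_coordinates(flt$matrix)

write_tsv(data.frame(sample = names(factors), factor = factors),
          res_path("matrix", "tmm_factors.tsv"))
write_tsv(data.frame(ogg = rownames(flt$matrix),
                     flt$matrix[, kept, drop = FALSE],
                     check.names = FALSE),
          res_path("matrix", "ogg_expression.tsv"))
write_tsv(flt$removed, res_path("matrix", "removed_oggs.tsv"))
write_tsv(data.frame(sample = rownames(mds), mds),
          res_path("matrix", "mds_coordinates.tsv"))

cat("TMM factors span [", round(min(factors), 3), ",",
    round(max(factors), 3), "]\n")
cat("Filter removed", nrow(flt$removed), "of", nrow(ogg_expr), "OGGs (",
    sum(flt$removed$reason == "zero variance"), "zero variance,",
    sum(flt$removed$reason != "zero variance"), "missingness );",
    nrow(flt$matrix), "retained\n")
cat("Outlier samples:",
    if (length(outliers)) paste(outliers, collapse = ", ") else "none",
    "\n")
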