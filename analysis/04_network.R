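# Stage 4: weighted co-expression network and module detection.
#
# Scale-free soft-threshold scan (beta = 8 is used when it reaches the 0.9
# fit target), unsigned adjacency, topological overlap, average-linkage
# module detection (minimum size 30), eigengene-based merging at
# dissimilarity 0.2, eigengenes and connectivity.

source("analysis/00_common.R")

expr <- read_counts_matrix(res_path("matrix", "ogg_expression.tsv"))

scan <- pick_soft_threshold(expr, candidate_powers = c(1:10, 12, 14, 16),
                            r2_target = 0.9)
write_tsv(scan$fit_table, res_path("network", "soft_threshold_fit.tsv"))
cat("Scale-free scan picked power", scan$power, "\n")

adj <- adjacency(expr, power = 8)
tom <- topological_overlap(adj)
labels <- cluster_modules(tom, min_module_size = 30)
labels <- merge_modules(expr, labels, merge_cutoff = 0.2)
eg <- module_eigengenes(expr, labels)
conn <- connectivity(adj, labels)

write_tsv(data.frame(ogg = names(labels), module = as.integer(labels)),
          res_path("network", "module_assignment.tsv"))
write_tsv(data.frame(module = rownames(eg$eigengenes), eg$eigengenes,
                     check.names = FALSE),
          res_path("network", "eigengenes.tsv"))
write_tsv(conn, res_path("network", "connectivity.tsv"))

sizes <- table(labels[labels > 0])
cat("Detected", length(sizes), "modules; sizes",
    paste(sort(as.integer(sizes), decreasing = TRUE), collapse = " "),
    "; unassigned", sum(labels == 0), "\n")
truth <- jsonlite::read_json(res_path("data", "truth.json"),
                             simplifyVector = TRUE)
tl <- setNames(truth$module, truth$ogg)
cat("Adjusted Rand index vs planted modules:",
    round(adjusted_rand_index(labels, tl[names(labels)]), 3), "\n")
cat("Variance explained by eigengenes:",
    paste(round(eg$var_explained, 2), collapse = " "), "\n")
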