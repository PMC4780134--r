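# Stage 8: functional enrichment of modules and preservation against the
# planted partition.
#
# Hypergeometric term enrichment per detected module over a synthetic
# annotation map, and a Fisher cross-tabulation of detected vs planted
# module memberships with joint BH correction.

source("analysis/00_common.R")

assign_tab <- read_tsv(res_path("network", "module_assignment.tsv"))
labels <- setNames(assign_tab$module, assign_tab$ogg)
truth <- jsonlite::read_json(res_path("data", "truth.json"),
                             simplifyVector = TRUE)

annot <- simulate_annotations(length(truth$ogg), n_terms = 200,
                              terms_per_gene = 5, seed = SEED + 503)
enrich <- do.call(rbind, lapply(sort(unique(labels[labels > 0])),
  function(m) data.frame(module = paste0("ME", m),
                         hypergeometric_enrichment(
                           names(labels)[labels == m], annot))))
write_tsv(enrich, res_path("stats", "enrichment.tsv"))
cat("Enriched terms at q < 0.05 (random annotations, expect ~none):",
    sum(enrich$q < 0.05), "of", nrow(enrich), "tests\n")

planted <- setNames(truth$module, truth$ogg)
pres <- module_preservation(labels, planted[names(labels)])
write_tsv(pres$significant_pairs,
          res_path("stats", "preservation_pairs.tsv"))
cat("Detected-vs-planted preservation:",
    nrow(pres$significant_pairs), "significant module pairs covering",
    length(unique(pres$significant_pairs$module_a)),
    "detected modules\n")
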