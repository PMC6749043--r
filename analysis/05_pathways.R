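#!/usr/bin/env Rscript
# Stage 5: pathway screening and the metabolite-protein network.
#
# Maps the shared reversed biomarkers to KEGG compound identifiers,
# scores the packaged pathway graphs by hypergeometric over-representation
# and topology impact (relative betweenness of matched nodes), retains
# pathways with impact > 0.1, and assembles the curated metabolite-protein
# network restricted to the biomarkers.

suppressPackageStartupMessages(library(nmrmetab))

biomarkers <- utils::read.csv("results/shared_biomarkers.csv")$metabolite
compounds <- map_to_compounds(biomarkers)
message(sprintf("%d of %d biomarkers map to compound identifiers",
                length(compounds), length(biomarkers)))

pathways <- load_pathways()
res <- pathway_results(compounds, pathways)
screened <- screen_pathways(res, impact_threshold = 0.1)
utils::write.csv(res, "results/pathway_results.csv", row.names = FALSE)
utils::write.csv(screened, "results/pathways_screened.csv",
                 row.names = FALSE)
message(sprintf("%d of %d pathways screened at impact > 0.1:",
                nrow(screened), nrow(res)))
for (i in seq_len(nrow(screened))) {
  message(sprintf("  %-45s impact %.2f  p %.3g", screened$name[i],
                  screened$impact[i], screened$enrichment_p[i]))
}

net <- build_metabolite_protein_network(biomarkers)
utils::write.csv(net$edges, "results/metabolite_protein_edges.csv",
                 row.names = FALSE)
message(sprintf("metabolite-protein network: %d edges over %d proteins",
                nrow(net$edges), length(unique(net$edges$protein))))
message("wrote results/pathway_results.csv, results/pathways_screened.csv")
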