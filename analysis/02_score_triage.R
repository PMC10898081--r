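#!/usr/bin/env Rscript
# Step 2 — delta-score ingestion and physiological-relevance triage.
#
# Reads the packaged per-SNV SpliceAI score table for the 67 assayed
# variants, resolves each reported offset to its pre-mRNA position, applies
# the relevance filter (loss scores must point at a documented isoform
# splice site), and reports which scores the filter discards.

library(satsplice)
dir.create("results", showWarnings = FALSE)

gm <- spink1_gene_model()
sc <- apply_relevance_filter(spink1_scores(gm), gm, verbose = TRUE)

masked <- sc[!(sc$rel_al & sc$rel_dl), ]
cat(sprintf("%d of %d variants carry a masked loss score\n", nrow(masked),
            nrow(sc)))
cat(sprintf("c.26T>G: raw DL %.2f -> max relevant score %.2f\n",
            sc$dl[sc$hgvs_c == "c.26T>G"],
            sc$max_relevant[sc$hgvs_c == "c.26T>G"]))

keep <- c("exon", "hgvs_c", "hgvs_p", "ag", "al", "dg", "dl",
          "al_site", "dl_site", "rel_al", "rel_dl", "max_relevant",
          "driving", "phase")
write.table(sc[keep], "results/spink1_scores_triaged.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/spink1_scores_triaged.tsv\n")
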