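#!/usr/bin/env Rscript
# Stage 6: gene-set enrichment. Each direction's gene list (all manifest
# annotations of its filtered CpGs) is tested against the gene sets by the
# upper-tail hypergeometric distribution over the manifest gene universe;
# significance requires overlap >= 5, nominal p < 0.01 and
# Benjamini-Hochberg p < 0.05.

suppressPackageStartupMessages(library(methylodrift))

sig <- utils::read.delim("results/diffmeth_filtered.tsv",
                         stringsAsFactors = FALSE)
manifest <- read_manifest("results/data/manifest.csv")
gene_sets <- read_gmt("results/data/gene_sets.gmt")

long <- expand_gene_annotations(manifest)
universe <- unique(long$gene[!is.na(long$gene)])
res <- list()
for (d in c("age_methylated", "age_demethylated")) {
  ids <- sig$probe_id[sig$direction == d]
  genes <- unique(long$gene[long$probe_id %in% ids & !is.na(long$gene)])
  cat(sprintf("%s: %d CpGs -> %d genes\n", d, length(ids), length(genes)))
  er <- hypergeom_enrichment(genes, gene_sets, universe)
  er$group <- d
  res[[d]] <- er
}
etab <- do.call(rbind, c(res, list(make.row.names = FALSE)))
write_table_tsv(etab, "results/enrichment.tsv")

hits <- etab[etab$significant, ]
cat("Significant gene sets:", nrow(hits), "\n")
if (nrow(hits) > 0) print(hits[, c("set", "group", "k", "K", "p", "p_bh")],
                          digits = 3)
cat("Wrote results/enrichment.tsv\n")
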