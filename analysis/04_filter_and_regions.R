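#!/usr/bin/env Rscript
# Stage 4: post-hoc filtering of the significant set (SNP-in-probe MAF >
# 0.01, then cell-type classifier CpGs), direction counts, and
# age-modified region calling (>= 2 same-direction significant CpGs in
# one annotated gene; span = outermost probe distance).

suppressPackageStartupMessages(library(methylodrift))

tab <- utils::read.delim("results/diffmeth.tsv", stringsAsFactors = FALSE)
snps <- read_snp_table("results/data/snp_table.csv")
classifier <- read_classifier_list("results/data/celltype_classifier.txt")
manifest <- read_manifest("results/data/manifest.csv")

sig <- tab[tab$direction != "not_significant", ]
f1 <- filter_snp_probes(sig, snps)
print(f1$report)
f2 <- filter_celltype_probes(f1$table, classifier)
print(f2$report)

cascade <- data.frame(
  stage = c("significant", "snp_maf", "celltype_classifier"),
  n_in = c(nrow(tab), f1$report$n_in, f2$report$n_in),
  n_excluded = c(nrow(tab) - nrow(sig), f1$report$n_excluded,
                 f2$report$n_excluded),
  n_retained = c(nrow(sig), f1$report$n_retained, f2$report$n_retained))
write_table_tsv(cascade, "results/filter_cascade.tsv")
write_table_tsv(f2$table, "results/diffmeth_filtered.tsv")

cnt <- classify_direction_counts(f2$table)
cat(sprintf("After filtering: %d CpGs (%d age-methylated, %d age-demethylated)\n",
            nrow(f2$table), cnt["n_methylated"], cnt["n_demethylated"]))

regions <- call_regions(f2$table, manifest)
write_table_tsv(regions, "results/regions.tsv")
cat("Age-modified regions:", nrow(regions), "\n")
if (nrow(regions) > 0) {
  cat(sprintf("  span %d..%d bp, %d..%d CpGs per region\n",
              min(regions$region_length_bp), max(regions$region_length_bp),
              min(regions$n_cpgs), max(regions$n_cpgs)))
}
cat("Wrote results/filter_cascade.tsv, results/diffmeth_filtered.tsv, results/regions.tsv\n")
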