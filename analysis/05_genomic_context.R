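#!/usr/bin/env Rscript
# Stage 5: genomic context of the filtered age-modified CpGs. Island /
# gene-structure / regulatory distributions per direction group,
# chromosome distribution against the array expectation, nearest-TSS
# distances, and the 2x2 direction contrasts (chi-square with Yates by
# default, Fisher alongside).

suppressPackageStartupMessages(library(methylodrift))

sig <- utils::read.delim("results/diffmeth_filtered.tsv",
                         stringsAsFactors = FALSE)
manifest <- read_manifest("results/data/manifest.csv")
gene_model <- utils::read.csv("results/data/gene_model.csv",
                              stringsAsFactors = FALSE)

loc <- location_distribution(sig, manifest)
write_table_tsv(loc, "results/location_distribution.tsv")
isl <- loc[loc$category_type == "island_relation" & loc$category == "Island", ]
cat(sprintf("In CpG islands: %.1f%% of age-methylated vs %.1f%% of age-demethylated\n",
            100 * isl$fraction[isl$group == "age_methylated"],
            100 * isl$fraction[isl$group == "age_demethylated"]))

chrd <- chromosome_distribution(sig, manifest)
write_table_tsv(chrd$table, "results/chromosome_distribution.tsv")
cat(sprintf("Observed-vs-expected chromosome correlation r = %.3f\n",
            chrd$pearson_r))

td <- nearest_tss(manifest[manifest$probe_id %in% sig$probe_id, ],
                  gene_model)
td$direction <- sig$direction[match(td$probe_id, sig$probe_id)]
write_table_tsv(td, "results/tss_distance.tsv")
hit <- td[!td$no_tss, ]
cat("TSS-distance bins (fractions per group):\n")
print(round(prop.table(table(hit$direction, as.character(hit$bin)),
                       margin = 1), 3))

mk <- function(d) manifest[manifest$probe_id %in%
                             sig$probe_id[sig$direction == d], ]
m <- mk("age_methylated"); dm <- mk("age_demethylated")
contrasts <- list(
  island = chi2_2x2(contingency_2x2(
    sum(m$island_relation == "Island"), nrow(m),
    sum(dm$island_relation == "Island"), nrow(dm))),
  promoter = chi2_2x2(contingency_2x2(
    sum(startsWith(m$regulatory_feature, "Promoter")), nrow(m),
    sum(startsWith(dm$regulatory_feature, "Promoter")), nrow(dm))),
  dhs = chi2_2x2(contingency_2x2(sum(m$dhs), nrow(m), sum(dm$dhs),
                                 nrow(dm))))
ctab <- do.call(rbind, lapply(names(contrasts), function(nm)
  data.frame(feature = nm, chi2 = contrasts[[nm]]$chi2,
             p = contrasts[[nm]]$p, fisher_p = contrasts[[nm]]$fisher_p)))
write_table_tsv(ctab, "results/direction_contrasts.tsv")
cat("Direction contrasts (methylated vs demethylated):\n")
print(ctab, digits = 3)
cat("Wrote results/location_distribution.tsv, chromosome_distribution.tsv, tss_distance.tsv, direction_contrasts.tsv\n")
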