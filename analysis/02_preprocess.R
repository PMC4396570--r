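#!/usr/bin/env Rscript
# Stage 2: preprocessing. Quantile-normalize the beta matrix across
# samples (every sample gets the mean order-statistic distribution), then
# transform to M values for modelling. Normalization happens on the beta
# scale; the M transform follows.

suppressPackageStartupMessages(library(methylodrift))

ds <- read_dataset("results/data/beta_matrix.tsv",
                   "results/data/sample_sheet.csv")
cat("Read", nrow(ds$values), "probes x", ncol(ds$values), "samples\n")

norm <- quantile_normalize(ds$values)
attr(norm, "n_imputed") <- NULL
ds_norm <- meth_dataset(norm, ds$samples, scale = "beta")
ds_m <- convert_scale(ds_norm, "M")

dir.create("results", showWarnings = FALSE)
write_matrix_tsv(ds_m$values, "results/m_values.tsv")

cat("Column beta means before normalization: range",
    sprintf("%.4f..%.4f", min(colMeans(ds$values)),
            max(colMeans(ds$values))), "\n")
cat("After normalization all columns share one distribution; mean beta",
    sprintf("%.4f", mean(norm)), "\n")
cat("Wrote results/m_values.tsv (M scale)\n")
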