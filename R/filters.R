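# Post-hoc exclusion cascade applied to the significant CpG set:
# SNP-in-probe minor-allele-frequency filter, then cell-type-classifier
# filter. Filters operate on the called table only; the testing universe
# (all probes on the manifest) is left untouched for enrichment.

filter_report <- function(stage, table_in, excluded_ids, reason) {
  structure(list(
    stage = stage,
    n_in = nrow(table_in),
    n_excluded = length(excluded_ids),
    n_retained = nrow(table_in) - length(excluded_ids),
    excluded = data.frame(probe_id = excluded_ids,
                          reason = rep_len(reason, length(excluded_ids)),
                          stringsAsFactors = FALSE)),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter '%s': %d in -> %d retained, %d excluded\n",
              x$stage, x$n_in, x$n_retained, x$n_excluded))
  invisible(x)
}

#' Filter significant CpGs carrying a common SNP in the probe
#'
#' A probe is excluded if and only if any SNP record tabulated for it has
#' minor allele frequency strictly above `maf_threshold`; a probe with no
#' SNP record, or only SNPs at or below the threshold, is retained.
#'
#' @param sig a `diffmeth_table` (typically pre-subset to significant
#'   probes, but any table works).
#' @param snps SNP table data.frame with columns `probe_id` and `maf`
#'   (see [read_snp_table()]).
#' @param maf_threshold exclusion threshold, in `(0, 0.5]`; default 0.01.
#' @return list with `table` (the retained rows) and `report`
#'   (a `filter_report`).
#' @export
filter_snp_probes <- function(sig, snps, maf_threshold = 0.01) {
  if (maf_threshold <= 0 || maf_threshold > 0.5) {
    stop("maf_threshold must be in (0, 0.5]")
  }
  if (!is.numeric(snps$maf) || anyNA(snps$maf) ||
      any(snps$maf < 0 | snps$maf > 0.5)) {
    stop("malformed MAF: values must be numeric in [0, 0.5]")
  }
  bad <- unique(snps$probe_id[snps$maf > maf_threshold])
  excl <- intersect(sig$probe_id, bad)
  out <- sig[!(sig$probe_id %in% excl), , drop = FALSE]
  list(table = out,
       report = filter_report("snp_maf", sig, excl,
                              sprintf("SNP in probe with MAF > %g",
                                      maf_threshold)))
}

#' Filter significant CpGs that are cell-type classifiers
#'
#' Removes probes appearing in a supplied list of CpG sites known to be
#' differentially methylated between sorted leukocyte populations, which
#' would otherwise confound whole-blood comparisons.
#'
#' @param sig a `diffmeth_table`.
#' @param classifier character vector of classifier probe ids (non-empty).
#' @return list with `table` and `report` as in [filter_snp_probes()].
#' @export
filter_celltype_probes <- function(sig, classifier) {
  if (length(classifier) == 0) stop("classifier list is empty")
  excl <- intersect(sig$probe_id, classifier)
  out <- sig[!(sig$probe_id %in% excl), , drop = FALSE]
  list(table = out,
       report = filter_report("celltype_classifier", sig, excl,
                              "cell-type classifier CpG"))
}

#' Count age-methylated vs age-demethylated probes
#'
#' Partitions the (filtered) significant probes by the sign of their
#' logfc. Significant probes with logfc exactly zero are counted
#' separately in the `n_zero` attribute and flagged with a warning.
#'
#' @param sig a `diffmeth_table`, typically filtered to significant rows.
#' @return named integer vector `c(n_methylated, n_demethylated)` with
#'   attribute `n_zero`.
#' @export
classify_direction_counts <- function(sig) {
  called <- sig[sig$direction != "not_significant", , drop = FALSE]
  n_zero <- sum(called$logfc == 0)
  if (n_zero > 0) {
    warning(n_zero, " significant probe(s) with zero logfc counted separately")
  }
  out <- c(n_methylated = sum(called$logfc > 0),
           n_demethylated = sum(called$logfc < 0))
  attr(out, "n_zero") <- n_zero
  out
}
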