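# Contingency contrasts between the age-methylated and age-demethylated
# sets, and gene-set hypergeometric enrichment with Benjamini-Hochberg
# control. Both the Yates-corrected and uncorrected chi-square are
# first-class: 2x2 contrasts default to the continuity correction, but
# either variant can be requested.

#' Pearson chi-square test on a 2x2 table
#'
#' Computes `sum((|O - E| - c)^2 / E)` with `c = 0.5` under the Yates
#' continuity correction (the default for 2x2 tables) and `c = 0`
#' otherwise, referred to chi-square with 1 degree of freedom. Fisher's
#' exact two-sided p is always computed alongside. If any margin is zero
#' the chi-square is undefined: the result carries `chi2 = NA` with
#' `zero_margin = TRUE` and only the Fisher p is usable.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param yates apply the continuity correction? Default `TRUE`.
#' @return list of class `contingency_result`: `observed`, `chi2`, `p`,
#'   `yates`, `fisher_p`, `zero_margin`.
#' @export
chi2_2x2 <- function(table, yates = TRUE) {
  if (!is.matrix(table) || !all(dim(table) == 2)) stop("need a 2x2 matrix")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  fisher_p <- fisher_exact_2x2(table)
  zero_margin <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  if (zero_margin) {
    warning("zero margin: chi-square undefined, use the Fisher p")
    chi2 <- NA_real_; p <- NA_real_
  } else {
    ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
    chi2 <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(observed = table, chi2 = chi2, p = p, yates = yates,
                 fisher_p = fisher_p, zero_margin = zero_margin),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("2x2 contrast: chi2 = %s (%s), p = %s; Fisher p = %s\n",
              format(x$chi2, digits = 4),
              if (x$yates) "Yates-corrected" else "uncorrected",
              format(x$p, digits = 3), format(x$fisher_p, digits = 3)))
  invisible(x)
}

#' Fisher's exact test (two-sided) on a 2x2 table
#'
#' Two-sided p: the sum of hypergeometric probabilities, over all tables
#' with the observed margins, that are no more probable than the observed
#' table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == 2)) stop("need a 2x2 matrix")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  stats::fisher.test(table)$p.value
}

#' Build a 2x2 table from group sizes and in-category counts
#'
#' Convenience for contrasting a binary annotation between two groups:
#' rows are groups, columns are in-category / not-in-category.
#'
#' @param k1,n1 in-category count and total for group 1.
#' @param k2,n2 in-category count and total for group 2.
#' @return 2x2 integer matrix.
#' @export
contingency_2x2 <- function(k1, n1, k2, n2) {
  matrix(as.integer(c(k1, n1 - k1, k2, n2 - k2)), nrow = 2, byrow = TRUE,
         dimnames = list(group = c("group1", "group2"),
                         status = c("in", "out")))
}

#' Gene-set hypergeometric enrichment
#'
#' Upper-tail hypergeometric test per gene set: with universe size `N`,
#' set size `K` (after intersecting the set with the universe), input-list
#' size `n` and overlap `k`, the p-value is `P[X >= k]` for
#' `X ~ Hypergeometric(N, K, n)`. P-values are Benjamini-Hochberg
#' adjusted over the tested sets. A record is flagged significant only if
#' `k >= min_overlap` and `p < p_cut` and `p_bh < bh_cut` — the overlap
#' floor keeps tiny sets from reaching significance on one or two genes.
#'
#' @param gene_list character vector, must be a subset of `universe`.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector of all eligible genes (e.g. all genes
#'   annotated on the manifest).
#' @param min_overlap minimum overlap for significance (default 5).
#' @param p_cut nominal p threshold (default 0.01).
#' @param bh_cut adjusted-p threshold (default 0.05).
#' @return data.frame ordered by p: `set`, `N`, `K`, `n`, `k`, `p`,
#'   `p_bh`, `significant`.
#' @export
hypergeom_enrichment <- function(gene_list, gene_sets, universe,
                                 min_overlap = 5, p_cut = 0.01,
                                 bh_cut = 0.05) {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (length(universe) == 0) stop("empty universe")
  if (length(gene_list) == 0) stop("empty gene list")
  stray <- setdiff(gene_list, universe)
  if (length(stray)) {
    stop("gene list not contained in universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  N <- length(universe); n <- length(gene_list)
  K <- vapply(gene_sets, function(s) length(intersect(s, universe)),
              integer(1))
  k <- vapply(gene_sets, function(s) length(intersect(s, gene_list)),
              integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_bh <- bh_adjust(p)
  out <- data.frame(set = names(gene_sets), N = N, K = K, n = n, k = k,
                    p = p, p_bh = p_bh,
                    significant = k >= min_overlap & p < p_cut &
                      p_bh < bh_cut,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort p ascending, multiply by
#' `m / rank`, enforce monotonicity from the largest rank down, cap at 1;
#' returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
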