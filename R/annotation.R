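# Genomic-context annotation of significant CpGs: nearest transcription
# start site, category distributions (island relation, gene structure,
# regulatory features) per direction group, and the chromosome-level
# comparison of observed vs array-expected frequencies.

#' Distance bins for absolute TSS distance (bp), half-open [lo, hi)
#' with the last bin closed at 1,000 kb.
#' @noRd
tss_bins <- function(absd) {
  cut(absd, breaks = c(0, 5e3, 5e4, 5e5, 1e6),
      labels = c("[0,5kb)", "[5,50kb)", "[50,500kb)", "[500,1000kb]"),
      right = FALSE, include.lowest = TRUE)
}

#' Nearest transcription start site per probe
#'
#' For each probe, finds the TSS with the smallest absolute distance on the
#' same chromosome within `max_distance` (default 1,000 kb). The signed
#' distance follows gene orientation: positive downstream of the TSS,
#' negative upstream (for a minus-strand gene, downstream means decreasing
#' coordinate). Exact distance ties are broken toward the gene the probe is
#' upstream of, then alphabetically by gene symbol, so results are
#' deterministic. Probes with no TSS in the window get `NA` distances and
#' `no_tss = TRUE`.
#'
#' @param probes data.frame with `probe_id`, `chromosome`, `position`
#'   (1-based bp).
#' @param gene_model data.frame with `gene`, `chromosome`, `tss`, `strand`
#'   (`"+"`/`"-"`).
#' @param max_distance search window in bp (default 1e6).
#' @return data.frame: `probe_id`, `nearest_gene`, `signed_distance_bp`,
#'   `abs_distance_bp`, `bin`, `no_tss`.
#' @export
nearest_tss <- function(probes, gene_model, max_distance = 1e6) {
  if (nrow(gene_model) == 0) stop("empty gene model")
  stopifnot(all(c("probe_id", "chromosome", "position") %in% names(probes)),
            all(c("gene", "chromosome", "tss", "strand") %in% names(gene_model)))
  np <- nrow(probes)
  out <- data.frame(probe_id = probes$probe_id,
                    nearest_gene = rep(NA_character_, np),
                    signed_distance_bp = rep(NA_real_, np),
                    abs_distance_bp = rep(NA_real_, np),
                    stringsAsFactors = FALSE)
  for (ch in unique(probes$chromosome)) {
    gi <- which(gene_model$chromosome == ch)
    pi <- which(probes$chromosome == ch)
    if (length(gi) == 0 || length(pi) == 0) next
    gm <- gene_model[gi, , drop = FALSE]
    for (k in pi) {
      pos <- probes$position[k]
      absd <- abs(pos - gm$tss)
      best <- min(absd)
      if (best > max_distance) next
      cand <- which(absd == best)
      if (length(cand) > 1) {
        signed <- ifelse(gm$strand[cand] == "+", pos - gm$tss[cand],
                         gm$tss[cand] - pos)
        up <- signed < 0
        if (any(up)) cand <- cand[up]
        cand <- cand[order(gm$gene[cand])][1]
      }
      out$nearest_gene[k] <- gm$gene[cand]
      out$signed_distance_bp[k] <- if (gm$strand[cand] == "+")
        pos - gm$tss[cand] else gm$tss[cand] - pos
      out$abs_distance_bp[k] <- best
    }
  }
  out$bin <- tss_bins(out$abs_distance_bp)
  out$no_tss <- is.na(out$abs_distance_bp)
  out
}

#' Category distributions of significant CpGs per direction group
#'
#' For the two direction groups (age-methylated, age-demethylated),
#' tabulates:
#' \itemize{
#'   \item gene-structure locations (TSS1500, TSS200, 5'UTR, 1stExon,
#'     Body, 3'UTR, Intergenic) over all (probe, annotation) pairs — a
#'     probe annotated to two transcripts contributes twice, and the
#'     denominator is the group's annotation count;
#'   \item island relation, promoter association (regulatory-feature
#'     prefix), DHS, enhancer and DMR class over probes, with the group's
#'     probe count as denominator.
#' }
#'
#' @param sig a `diffmeth_table`; rows with direction `age_methylated` or
#'   `age_demethylated` are used.
#' @param manifest probe annotation data.frame.
#' @return data.frame: `group`, `category_type`, `category`, `count`,
#'   `denominator`, `fraction`.
#' @export
location_distribution <- function(sig, manifest) {
  groups <- c("age_methylated", "age_demethylated")
  called <- sig[sig$direction %in% groups, , drop = FALSE]
  long <- expand_gene_annotations(manifest)
  region_vocab <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR",
                    "Intergenic")
  island_vocab <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                    "OpenSea")
  bad_region <- setdiff(unique(long$region), region_vocab)
  if (length(bad_region)) {
    stop("unknown gene-structure category: ",
         paste(bad_region, collapse = ", "))
  }
  bad_island <- setdiff(unique(manifest$island_relation), island_vocab)
  if (length(bad_island)) {
    stop("unknown island-relation category: ",
         paste(bad_island, collapse = ", "))
  }
  res <- list()
  for (gp in groups) {
    ids <- called$probe_id[called$direction == gp]
    ann <- long[long$probe_id %in% ids, , drop = FALSE]
    n_ann <- nrow(ann)
    cnt <- table(factor(ann$region, levels = region_vocab))
    res[[length(res) + 1]] <- data.frame(
      group = gp, category_type = "gene_structure",
      category = names(cnt), count = as.integer(cnt),
      denominator = n_ann,
      fraction = if (n_ann > 0) as.numeric(cnt) / n_ann else NA_real_,
      stringsAsFactors = FALSE)
    mf <- manifest[manifest$probe_id %in% ids, , drop = FALSE]
    n_probe <- nrow(mf)
    icnt <- table(factor(mf$island_relation, levels = island_vocab))
    res[[length(res) + 1]] <- data.frame(
      group = gp, category_type = "island_relation",
      category = names(icnt), count = as.integer(icnt),
      denominator = n_probe,
      fraction = if (n_probe > 0) as.numeric(icnt) / n_probe else NA_real_,
      stringsAsFactors = FALSE)
    flags <- c(
      promoter_associated = sum(startsWith(mf$regulatory_feature, "Promoter")),
      dhs = sum(mf$dhs), enhancer = sum(mf$enhancer),
      dmr = sum(nzchar(mf$dmr_class)))
    res[[length(res) + 1]] <- data.frame(
      group = gp, category_type = "regulatory",
      category = names(flags), count = as.integer(flags),
      denominator = n_probe,
      fraction = if (n_probe > 0) as.numeric(flags) / n_probe else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Chromosome distribution of significant CpGs vs array expectation
#'
#' Compares the fraction of significant probes per chromosome with the
#' fraction of all manifest probes per chromosome, and reports their
#' Pearson correlation across chromosomes.
#'
#' @param sig a `diffmeth_table`; rows with a direction call are used.
#' @param manifest probe annotation data.frame covering all tested probes.
#' @return list with `table` (data.frame `chromosome`, `n_observed`,
#'   `observed_fraction`, `n_expected_pool`, `expected_fraction`) and
#'   `pearson_r` (`NA` with a warning if fewer than 2 chromosomes).
#' @export
chromosome_distribution <- function(sig, manifest) {
  called <- sig[sig$direction != "not_significant", , drop = FALSE]
  chr_sig <- manifest$chromosome[match(called$probe_id, manifest$probe_id)]
  if (anyNA(chr_sig)) {
    stop("significant probe(s) absent from manifest: ",
         paste(utils::head(called$probe_id[is.na(chr_sig)], 5), collapse = ", "))
  }
  chroms <- unique(manifest$chromosome)
  chrnum <- suppressWarnings(as.integer(sub("^chr", "", chroms)))
  chroms <- chroms[order(chrnum, chroms)]
  n_exp <- table(factor(manifest$chromosome, levels = chroms))
  n_obs <- table(factor(chr_sig, levels = chroms))
  tab <- data.frame(
    chromosome = chroms,
    n_observed = as.integer(n_obs),
    observed_fraction = as.numeric(n_obs) / max(1, sum(n_obs)),
    n_expected_pool = as.integer(n_exp),
    expected_fraction = as.numeric(n_exp) / sum(n_exp),
    stringsAsFactors = FALSE)
  if (length(chroms) < 2) {
    warning("fewer than 2 chromosomes: correlation undefined")
    r <- NA_real_
  } else if (stats::sd(tab$observed_fraction) == 0 ||
             stats::sd(tab$expected_fraction) == 0) {
    r <- NA_real_  # e.g. no significant probes at all
  } else {
    r <- stats::cor(tab$observed_fraction, tab$expected_fraction)
  }
  list(table = tab, pearson_r = r)
}
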