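# End-to-end orchestration: simulate or ingest, preprocess, test, filter,
# call regions, annotate, enrich — writing every stage output plus a
# machine-readable summary into a run directory.

# small stable hash (polynomial rolling hash over the deparsed config,
# modulo a Mersenne prime) for the summary
hash_config <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Either `sim` (a [sim_config()], simulation mode) or `paths` (a named
#' list of input files: `matrix`, `samples`, `manifest`, `gene_model`,
#' `snps`, `classifier`, `gene_sets`) must be supplied.
#'
#' @param sim a [sim_config()] for simulation mode, or `NULL`.
#' @param paths named list of input paths for ingestion mode, or `NULL`.
#' @param normalize quantile-normalize the beta matrix before the M
#'   transform? Default `TRUE`.
#' @param contrast_ages the two ages (months) to contrast; `NULL` means
#'   first and last observed.
#' @param alpha Bonferroni-corrected significance level (default 0.01).
#' @param maf_threshold SNP filter threshold (default 0.01).
#' @param chi2_yates default continuity-correction setting for the 2x2
#'   contrasts (default `TRUE`).
#' @param min_overlap,p_cut,bh_cut enrichment significance rule.
#' @param out_dir run directory for stage outputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL, normalize = TRUE,
                            contrast_ages = NULL, alpha = 0.01,
                            maf_threshold = 0.01, chi2_yates = TRUE,
                            min_overlap = 5, p_cut = 0.01, bh_cut = 0.05,
                            out_dir = tempfile("methylodrift_run_")) {
  if (is.null(sim) == is.null(paths)) {
    stop("supply exactly one of 'sim' (simulation mode) or 'paths'")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (!is.null(paths)) {
    req <- c("matrix", "samples", "manifest", "gene_model", "snps",
             "classifier", "gene_sets")
    miss <- setdiff(req, names(paths))
    if (length(miss)) stop("paths missing: ", paste(miss, collapse = ", "))
    absent <- unlist(paths[req])[!file.exists(unlist(paths[req]))]
    if (length(absent)) stop("input file(s) not found: ",
                             paste(absent, collapse = ", "))
  }
  structure(list(sim = sim, paths = paths, normalize = normalize,
                 contrast_ages = contrast_ages, alpha = alpha,
                 maf_threshold = maf_threshold, chi2_yates = chi2_yates,
                 min_overlap = min_overlap, p_cut = p_cut, bh_cut = bh_cut,
                 out_dir = out_dir), class = "pipeline_config")
}

stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full longitudinal differential-methylation pipeline
#'
#' Executes, in fixed order: data simulation or ingestion; optional
#' quantile normalization (on the beta scale) and conversion to M values;
#' per-probe model fits, prior estimation and the moderated t-test;
#' SNP-MAF and cell-type-classifier filtering of the significant set;
#' direction counts; age-modified region calling; genomic-context
#' distributions, chromosome correlation and 2x2 direction contrasts; and
#' gene-set enrichment of each direction's gene list against the manifest
#' gene universe. All stage outputs are written under `config$out_dir`
#' together with `summary.json`. Reruns with the same config are
#' bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  inputs <- stage("ingest", {
    if (!is.null(config$sim)) {
      sim <- generate_dataset(config$sim)
      write_simulated_data(sim, out("input"))
      list(dataset = sim$dataset, manifest = sim$manifest,
           gene_model = sim$gene_model, snps = sim$snps,
           classifier = sim$classifier, gene_sets = sim$gene_sets,
           truth = sim$truth)
    } else {
      p <- config$paths
      list(dataset = read_dataset(p$matrix, p$samples, scale = "beta"),
           manifest = read_manifest(p$manifest),
           gene_model = utils::read.csv(p$gene_model,
                                        stringsAsFactors = FALSE),
           snps = read_snp_table(p$snps),
           classifier = read_classifier_list(p$classifier),
           gene_sets = read_gmt(p$gene_sets),
           truth = NULL)
    }
  })

  dataset <- stage("preprocess", {
    ds <- inputs$dataset
    if (config$normalize) {
      v <- quantile_normalize(ds$values)
      attr(v, "n_imputed") <- NULL
      ds <- meth_dataset(v, ds$samples, scale = "beta")
    }
    ds <- convert_scale(ds, "M")
    write_matrix_tsv(ds$values, out("m_values.tsv"))
    ds
  })

  dm <- stage("test", {
    fits <- fit_probe_models(dataset, contrast_ages = config$contrast_ages)
    prior <- estimate_prior(fits)
    tab <- moderated_t(fits, prior, alpha = config$alpha)
    write_table_tsv(tab, out("diffmeth.tsv"))
    list(fits = fits, prior = prior, table = tab)
  })

  filt <- stage("filter", {
    sig <- dm$table[dm$table$direction != "not_significant", , drop = FALSE]
    f1 <- filter_snp_probes(sig, inputs$snps,
                            maf_threshold = config$maf_threshold)
    f2 <- if (length(inputs$classifier) > 0) {
      filter_celltype_probes(f1$table, inputs$classifier)
    } else {  # nothing to contrast against: stage is a documented no-op
      list(table = f1$table,
           report = structure(list(stage = "celltype_classifier",
                                   n_in = nrow(f1$table), n_excluded = 0L,
                                   n_retained = nrow(f1$table),
                                   excluded = f1$report$excluded[0, ]),
                              class = "filter_report"))
    }
    cascade <- data.frame(
      stage = c("significant", "snp_maf", "celltype_classifier"),
      n_in = c(nrow(dm$table), f1$report$n_in, f2$report$n_in),
      n_excluded = c(nrow(dm$table) - nrow(sig), f1$report$n_excluded,
                     f2$report$n_excluded),
      n_retained = c(nrow(sig), f1$report$n_retained, f2$report$n_retained),
      stringsAsFactors = FALSE)
    write_table_tsv(cascade, out("filter_cascade.tsv"))
    jsonlite::write_json(
      list(cascade = cascade,
           excluded = rbind(f1$report$excluded, f2$report$excluded)),
      out("filter_report.json"), auto_unbox = TRUE, digits = NA)
    list(table = f2$table, cascade = cascade)
  })

  counts <- stage("direction_counts", classify_direction_counts(filt$table))

  regions <- stage("regions", {
    r <- call_regions(filt$table, inputs$manifest)
    write_table_tsv(r, out("regions.tsv"))
    r
  })

  annot <- stage("annotate", {
    loc <- location_distribution(filt$table, inputs$manifest)
    write_table_tsv(loc, out("location_distribution.tsv"))
    chrd <- chromosome_distribution(filt$table, inputs$manifest)
    write_table_tsv(chrd$table, out("chromosome_distribution.tsv"))
    sig_ids <- filt$table$probe_id
    mf <- inputs$manifest
    td <- nearest_tss(mf[mf$probe_id %in% sig_ids, , drop = FALSE],
                      inputs$gene_model)
    td$direction <- filt$table$direction[match(td$probe_id,
                                               filt$table$probe_id)]
    write_table_tsv(td, out("tss_distance.tsv"))
    # 2x2 direction contrasts on probe-level annotations
    pick <- function(d) mf[mf$probe_id %in%
                             sig_ids[filt$table$direction == d], , drop = FALSE]
    m <- pick("age_methylated"); dm_ <- pick("age_demethylated")
    contrasts <- list()
    if (nrow(m) > 0 && nrow(dm_) > 0) {
      feats <- list(
        island = function(z) z$island_relation == "Island",
        promoter_associated = function(z)
          startsWith(z$regulatory_feature, "Promoter"),
        dhs = function(z) z$dhs,
        enhancer = function(z) z$enhancer)
      for (nm in names(feats)) {
        f <- feats[[nm]]
        tb <- contingency_2x2(sum(f(m)), nrow(m), sum(f(dm_)), nrow(dm_))
        contrasts[[nm]] <- chi2_2x2(tb, yates = config$chi2_yates)
      }
    }
    ctab <- do.call(rbind, lapply(names(contrasts), function(nm) {
      x <- contrasts[[nm]]
      data.frame(feature = nm, chi2 = x$chi2, p = x$p,
                 fisher_p = x$fisher_p, yates = x$yates,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(ctab)) write_table_tsv(ctab, out("direction_contrasts.tsv"))
    list(location = loc, chromosome = chrd, tss = td, contrasts = contrasts)
  })

  enrich <- stage("enrich", {
    long <- expand_gene_annotations(inputs$manifest)
    universe <- unique(long$gene[!is.na(long$gene)])
    res <- list()
    for (d in c("age_methylated", "age_demethylated")) {
      ids <- filt$table$probe_id[filt$table$direction == d]
      genes <- unique(long$gene[long$probe_id %in% ids & !is.na(long$gene)])
      if (length(genes) > 0) {
        er <- hypergeom_enrichment(genes, inputs$gene_sets, universe,
                                   min_overlap = config$min_overlap,
                                   p_cut = config$p_cut,
                                   bh_cut = config$bh_cut)
        er$group <- d
        res[[d]] <- er
      }
    }
    etab <- if (length(res) > 0)
      do.call(rbind, c(res, list(make.row.names = FALSE))) else NULL
    if (!is.null(etab)) write_table_tsv(etab, out("enrichment.tsv"))
    etab
  })

  summary <- list(
    config_hash = hash_config(unclass(config)[setdiff(names(config),
                                                      "out_dir")]),
    n_samples = ncol(dataset$values),
    n_probes = nrow(dataset$values),
    contrast_ages = dm$fits$contrast_ages,
    prior = list(d0 = if (is.infinite(dm$prior$d0)) "Inf" else dm$prior$d0,
                 s02 = dm$prior$s02),
    n_significant = sum(dm$table$direction != "not_significant"),
    filter_cascade = filt$cascade,
    n_methylated = unname(counts["n_methylated"]),
    n_demethylated = unname(counts["n_demethylated"]),
    n_regions = nrow(regions),
    chromosome_r = annot$chromosome$pearson_r,
    n_enrichment_significant = if (is.null(enrich)) 0L
                               else sum(enrich$significant))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Write a human-readable report for a completed run
#'
#' Summarizes the filter cascade, the direction counts, the called
#' regions and the enrichment hits from the stage files in a run
#' directory. Incomplete runs produce a partial report with warnings.
#' Output contains no timestamps, so a rerun over identical stage files
#' is byte-identical.
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @param path report path; default `report.txt` inside `run_dir`.
#' @return invisibly, the report path.
#' @export
write_summary_report <- function(run_dir, path = file.path(run_dir,
                                                           "report.txt")) {
  lines <- c("methylodrift run report", strrep("=", 23), "")
  need <- function(f) {
    fp <- file.path(run_dir, f)
    if (!file.exists(fp)) {
      warning("missing stage output: ", f)
      return(NULL)
    }
    fp
  }
  fp <- need("summary.json")
  if (!is.null(fp)) {
    s <- jsonlite::read_json(fp)
    lines <- c(lines,
               sprintf("samples: %s   probes: %s", s$n_samples, s$n_probes),
               sprintf("contrast: %s vs %s months",
                       s$contrast_ages[[1]], s$contrast_ages[[2]]),
               sprintf("significant CpGs: %s (age-methylated %s, age-demethylated %s)",
                       s$n_significant, s$n_methylated, s$n_demethylated),
               "")
  }
  fp <- need("filter_cascade.tsv")
  if (!is.null(fp)) {
    fc <- utils::read.delim(fp)
    lines <- c(lines, "Filter cascade:",
               sprintf("  %-22s in=%4d excluded=%4d retained=%4d",
                       fc$stage, fc$n_in, fc$n_excluded, fc$n_retained), "")
  }
  fp <- need("regions.tsv")
  if (!is.null(fp)) {
    rg <- utils::read.delim(fp)
    lines <- c(lines, sprintf("Age-modified regions: %d", nrow(rg)))
    if (nrow(rg) > 0) {
      lines <- c(lines, sprintf("  %-10s %-17s %2d CpGs  %7d bp",
                                rg$gene, rg$direction, rg$n_cpgs,
                                rg$region_length_bp))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "Age-modified regions: (stage output missing)", "")
  }
  fp <- need("enrichment.tsv")
  if (!is.null(fp)) {
    en <- utils::read.delim(fp)
    hits <- en[en$significant, , drop = FALSE]
    lines <- c(lines, sprintf("Enrichment hits: %d", nrow(hits)))
    if (nrow(hits) > 0) {
      lines <- c(lines, sprintf("  %-20s %-17s k=%2d/%2d p=%.3g p_bh=%.3g",
                                hits$set, hits$group, hits$k, hits$K,
                                hits$p, hits$p_bh))
    }
  }
  if (all(c("Filter cascade:") %in% lines) &&
      !file.exists(file.path(run_dir, "regions.tsv"))) {
    lines <- c(lines, "", "downstream sections empty: no significant CpGs")
  }
  writeLines(lines, path)
  invisible(path)
}
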